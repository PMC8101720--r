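format-version: 1.2
! SYNTHETIC Disease Ontology slice. This is NOT a Disease Ontology
! release: it is a hand-built stand-in reproducing the is_a topology of
! the neurodegenerative-disease neighbourhood (motor neuron diseases,
! synucleinopathies, tauopathies, demyelinating diseases) so that the
! disease-level similarity machinery can be exercised offline. Term
! similarities computed on this slice approximate, but do not equal,
! values computed on a real DO release.

[Term]
id: DOID:4
name: disease

[Term]
id: DOID:7
name: disease of anatomical entity
is_a: DOID:4

[Term]
id: DOID:863
name: nervous system disease
is_a: DOID:7

[Term]
id: DOID:331
name: central nervous system disease
is_a: DOID:863

[Term]
id: DOID:1289
name: neurodegenerative disease
is_a: DOID:331

[Term]
id: DOID:1307
name: dementia
is_a: DOID:331

[Term]
id: DOID:3213
name: demyelinating disease
is_a: DOID:331

[Term]
id: DOID:231
name: motor neuron disease
is_a: DOID:1289

[Term]
id: DOID:0050890
name: synucleinopathy
is_a: DOID:1289

[Term]
id: DOID:680
name: tauopathy
is_a: DOID:1289

[Term]
id: DOID:332
name: amyotrophic lateral sclerosis
is_a: DOID:231

[Term]
id: DOID:12377
name: spinal muscular atrophy
is_a: DOID:231

[Term]
id: DOID:14330
name: Parkinson's disease
is_a: DOID:0050890

[Term]
id: DOID:12217
name: Lewy body dementia
is_a: DOID:0050890
is_a: DOID:1307

[Term]
id: DOID:10652
name: Alzheimer's disease
is_a: DOID:680
is_a: DOID:1307

[Term]
id: DOID:9255
name: frontotemporal dementia
is_a: DOID:680
is_a: DOID:1307

[Term]
id: DOID:12858
name: Huntington's disease
is_a: DOID:1289

[Term]
id: DOID:2377
name: multiple sclerosis
is_a: DOID:3213
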