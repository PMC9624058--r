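# Example scenario configuration: the phenotypic arm of the
# single-cohort design, run at desk scale.
architecture: rsa
generations: [discrete, overlapping]
criterion: [phenotype]
h2: [0.1, 0.5, 0.9]
reps: [1, 3]
n_replicates: 5
base_seed: 1
scale: reduced
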