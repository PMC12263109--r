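# Synthetic scorer backend: a deterministic stand-in for a language-model
# service, with injectable positional and literature biases.
backend: synthetic
signal: 2
beta_pos: 1.5
beta_lit: 0
noise_sd: 0.5
seed: 1
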