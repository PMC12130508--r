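# Toy profile: 5 subjects, short records, tiny models. End-to-end pipeline
# smoke runs (generate -> preprocess -> train -> shapley -> report) finish in
# minutes on one CPU.
device: smartwatch
n_subjects: 5
n_repetitions: 10
duration_steps: 64
dwell_steps: 3
channel_informativeness: [0.9, 0.7, 0.5, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2]
seed: 1
target_length: 64
input_length: 64
architecture: fcn
filters: [8, 16, 8]
train:
  epochs: 30
  batch_size: 16
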