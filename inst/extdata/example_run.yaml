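# Example run configuration: waking-state lattice driven by two pulse
# trains, recorded by a unit and an EEG-scale electrode.
grid: {nx: 100, ny: 100}
n_steps: 3000
seed: 1
params:
  c2: 2.6655
  f: 0.01
  g: 0.0001
  neighborhood: moore-8
  boundary: torus
stimuli:
  - {type: pulse_train, fundamental_hz: 7, node: [20, 50], amplitude: 5}
  - {type: pulse_train, fundamental_hz: 13, node: [20, 50], amplitude: 5}
electrodes:
  - {id: unit, center: [70, 50], radius_mm: 0.25}
  - {id: eeg, center: [70, 50], radius_mm: 2.5}
output:
  recordings_csv: recordings.csv
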