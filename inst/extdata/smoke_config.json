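{
  "seed": 42,
  "sim": { "N": 256, "n_frames": 4096, "dt": 5e-4 },
  "spectrum": { "segment_length": 1024 },
  "stages": { "simulate": true, "render": false, "segment": false,
              "stats": true, "spectrum": true, "rheology": true,
              "morphotype": true }
}
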