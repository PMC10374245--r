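{
  "description": "Example channel reordering for a 40-channel montage laid out as a 5 x 8 grid numbered row-major: a boustrophedon (snake) path that keeps spatially adjacent channels contiguous. Montages differ; supply the permutation matching your optode layout.",
  "n_channels": 40,
  "order": [1, 2, 3, 4, 5, 6, 7, 8, 16, 15, 14, 13, 12, 11, 10, 9, 17, 18, 19, 20, 21, 22, 23, 24, 32, 31, 30, 29, 28, 27, 26, 25, 33, 34, 35, 36, 37, 38, 39, 40]
}
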