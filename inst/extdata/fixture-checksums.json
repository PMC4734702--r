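{
  "tiny-pavlovian": "744135479",
  "single-neuron": "1000730371",
  "single-trial-detection": "227950719"
}
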