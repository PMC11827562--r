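{
  "command": "frobnicate",
  "args": [],
  "seed": null,
  "package": "voiplan",
  "version": "0.1.0",
  "started": "2026-09-12T06:06:04+0000",
  "finished": "2026-09-12T06:06:04+0000",
  "outputs": [],
  "warnings": [],
  "error": "unknown command: frobnicate"
}
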