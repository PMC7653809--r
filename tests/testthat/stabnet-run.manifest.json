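{
  "tool": "stabnet",
  "version": "0.1.0",
  "seed": 0,
  "config": {
    "m": 2,
    "nIter": 500,
    "alpha": 0.5,
    "kfolds": 5,
    "cutoff": 0.95,
    "seed": 0,
    "workers": 1,
    "delimiter": "\t",
    "orientation": "genes-in-columns",
    "fullTable": false,
    "strictCutoff": false,
    "noStandardize": false,
    "verbose": false
  },
  "inputs": {
    "input": null,
    "targets": null,
    "regulators": null
  },
  "started": "2026-09-26T07:26:37+0000",
  "finished": "2026-09-26T07:26:37+0000",
  "error": "--input and --output are required"
}
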