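{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "hgtrecon CLI report",
  "type": "object",
  "required": ["command", "status", "exit_code"],
  "properties": {
    "command": {
      "type": "string",
      "enum": ["validate-tree", "reconcile", "check-map", "check-exists",
               "dtl-convert", "aggregate", "simulate"]
    },
    "status": { "type": "string" },
    "exit_code": { "type": "integer", "enum": [0, 2, 3, 4] },
    "details": { "type": "object" }
  }
}
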