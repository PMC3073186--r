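SELECT * WHERE {?gene ?pred ?isbn FILTER regex (?isbn, "[0-9]19857[0-9]") .}
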