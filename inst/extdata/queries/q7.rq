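SELECT * WHERE {?gp rdf:type ?type FILTER regex (?gp, "0005[0-9][0-9][0-9]") .?gp rdfs:label ?name FILTER regex (?name, "activity") .?gp rdfs:comment ?comment FILTER regex (?comment, "molecular").}
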