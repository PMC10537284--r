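{"0": "rice", "1": "stewed_pork", "2": "fried_chicken"}
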