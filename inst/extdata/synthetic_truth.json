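{"J1":0.1,"J2":0.05,"tau":2,"eta0":200,"units":{"J1":"1/Pa","J2":"1/Pa","tau":"s","eta0":"Pa*s"}}
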