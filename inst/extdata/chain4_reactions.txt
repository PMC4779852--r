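# worked example: irreversible four-metabolite chain
r1: A -> B
r2: B -> C
r3: C -> D
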