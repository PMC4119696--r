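label,value
diamonds,0.5
diamonds,0.8
diamonds,0.6
diamonds,0.5
diamonds,0.4
diamonds,1
circles,0.4
circles,0.6
circles,0.7
circles,0.5
circles,0.8
circles,0.6
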