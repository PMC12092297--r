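term,weight
_intercept,0.0
sad,2.0
crying,1.5
hurt,1.2
afraid,1.0
pain,1.0
tired,0.6
happy,-1.5
good,-0.8
loved,-1.0
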