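((b,(a,c,b)c,d)a,(d,b,(b,c,a)c)a,(a,(b,c)b,((d)a,(b,c)b,(d)a)a)b)a;
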