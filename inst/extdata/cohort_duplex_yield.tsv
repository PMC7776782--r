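model	duplex_bp
big_blue	4716990836
tg_rasH2	4923565684
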