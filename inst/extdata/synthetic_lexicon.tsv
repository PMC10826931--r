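heroin	C0011892
heroin overdose	C0600290
naloxone	C0027358
fentanyl	C0015846
altered mental status	C0856054
respiratory depression	C0235063
substance	C0439861
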