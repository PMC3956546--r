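# US federal holidays, calendar year 2011 (observed dates)
2011-01-17
2011-02-21
2011-05-30
2011-07-04
2011-09-05
2011-10-10
2011-11-11
2011-11-24
2011-12-26
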