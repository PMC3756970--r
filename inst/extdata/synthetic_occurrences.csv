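latitude,longitude,date,source_id
24.70,-81.50,2005-03-14,SYNTH-001
25.10,-81.40,2005-07-02,SYNTH-002
25.60,-81.30,2006-01-21,SYNTH-003
24.90,-81.60,2006-09-08,SYNTH-004
25.30,-81.20,2007-05-30,SYNTH-005
26.10,-81.05,2008-11-11,SYNTH-006
24.58,-81.22,2010-04-19,SYNTH-007
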