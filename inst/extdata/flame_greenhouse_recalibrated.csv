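season,observed,gdd_total,predicted_gdd,days_total,predicted_calendar
2005,2005-06-02,1498,2005-06-05,133,2005-05-30
2006,2006-06-06,1625,2006-05-30,132,2006-06-04
2007,2007-06-05,1542,2007-06-05,128,2007-06-07
2008,2008-05-29,1503,2008-06-01,128,2008-05-31
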