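site,season,observed,predicted_gdd,predicted_calendar
open_field,2003,2003-07-11,2003-07-10,2003-07-07
open_field,2005,2005-07-03,2005-07-11,2005-07-16
open_field,2006,2006-07-10,2006-07-04,2006-07-05
open_field,2007,2007-07-09,2007-07-09,2007-07-06
open_field,2008,2008-07-14,2008-07-14,2008-07-12
greenhouse,2005,2005-06-02,2005-06-12,2005-05-17
greenhouse,2006,2006-06-06,2006-06-07,2006-05-21
greenhouse,2007,2007-06-05,2007-06-11,2007-05-25
greenhouse,2008,2008-05-29,2008-06-06,2008-05-18
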