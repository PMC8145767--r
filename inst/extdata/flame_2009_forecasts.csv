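site,season,reference,predicted,observed
open_field,2009,average_year,2009-07-12,2009-07-16
open_field,2009,tmy,2009-07-15,2009-07-16
greenhouse,2009,average_year,2009-06-06,2009-06-10
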