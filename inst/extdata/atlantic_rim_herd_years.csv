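herd,year,n,indiv_start_date,herd_start_date,max_simultaneous,median_displacement_km
NAR,2005,7,2005-04-09,2005-04-23,6,32
NAR,2006,8,2006-04-03,2006-04-21,5,28
NAR,2008,12,2008-04-30,2008-05-16,10,26
NAR,2009,8,2009-03-18,2009-05-08,7,23
NAR,2010,1,2010-05-05,2010-05-05,1,16
NAR,2015,11,2015-03-16,2015-03-27,5,34
NAR,2016,14,2016-04-04,2016-05-03,10,34
NAR,2017,16,2017-03-13,2017-04-17,9,21
NAR,2018,15,2018-04-11,2018-04-19,9,24
SAR,2005,21,2005-04-01,2005-04-16,16,37
SAR,2006,20,2006-03-27,2006-04-22,15,36
SAR,2008,9,2008-03-17,2008-05-15,9,30
SAR,2009,19,2009-02-28,2009-05-06,15,35
SAR,2010,11,2010-03-12,2010-05-08,9,56
SAR,2015,24,2015-01-20,2015-04-07,16,56
SAR,2016,20,2016-02-26,2016-04-22,15,68
SAR,2017,18,2017-02-18,2017-04-11,15,63
SAR,2018,19,2018-02-13,2018-04-22,15,46
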