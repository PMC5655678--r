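series_id,site,year,value
overwinter,mexico,1993,6.23
overwinter,mexico,1994,7.81
overwinter,mexico,1995,12.61
overwinter,mexico,1996,18.19
overwinter,mexico,1997,5.77
overwinter,mexico,1998,5.56
overwinter,mexico,1999,9.05
overwinter,mexico,2000,2.83
overwinter,mexico,2001,9.35
overwinter,mexico,2002,7.54
overwinter,mexico,2003,11.12
overwinter,mexico,2004,2.19
overwinter,mexico,2005,5.91
overwinter,mexico,2006,6.87
overwinter,mexico,2007,4.61
overwinter,mexico,2008,5.06
overwinter,mexico,2009,1.92
overwinter,mexico,2010,4.02
overwinter,mexico,2011,2.89
overwinter,mexico,2012,1.19
overwinter,mexico,2013,0.67
overwinter,mexico,2014,1.13
overwinter,mexico,2015,4.01
overwinter,mexico,2016,2.91
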