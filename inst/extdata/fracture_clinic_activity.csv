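financial_year,total_bookings,clinics_held,new_bookings,review_bookings,adult_bookings,pediatric_bookings,fta_count
2014-2015,321,31,175,146,279,42,53
2015-2016,1235,82,686,549,776,459,321
2016-2017,1136,82,612,524,915,221,318
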