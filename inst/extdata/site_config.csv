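# Survey-site configuration: elevations, overlap windows used for seasonal
# abundance totals, baseline/resurvey years, and years excluded from decade
# weather statistics (missing station months). Years are semicolon-separated.
site,elevation_m,overlap_start,overlap_end,baseline_years,resurvey_years,excluded_weather_years,weather_source
Chautauqua,1752,05-15,09-20,1959;1960,2007;2008,,NOAA-050848
A1,2195,05-15,09-20,1959,2007;2008,1959;2003,A1
B1,2591,05-15,09-26,1959;1960,2006;2007;2008,1956;2001;2002;2003,B1
C1,3048,06-01,09-07,1959;1960,2006;2007;2008,,C1
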