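# Grasshopper resurvey phenology table: Front Range (Colorado) elevational gradient.
# One row per focal egg-diapausing species per site. baseline_doy is the earliest
# day of year of adult appearance in the 1959-1960 surveys; delta_YYYY is the change
# in timing to adulthood (days; negative = earlier) in resurvey year YYYY relative
# to baseline_doy; blank = site not surveyed that year. gdd_baseline is the
# at-adulthood growing degree-day requirement in the baseline survey (base 12 C,
# cutoff 38 C; A1 values from 1959 only), gdd_se its standard error where available.
# Day-of-year is 1-based (Jan 1 = 1).
site,elevation_m,species,baseline_doy,delta_2006,delta_2007,delta_2008,gdd_baseline,gdd_se
Chautauqua,1752,Aeropedellus clavatus,152,,-11,4,232,
Chautauqua,1752,Melanoplus confusus,155,,0,1,274,
Chautauqua,1752,Melanoplus sanguinipes,176,,7,2,507,27
Chautauqua,1752,Melanoplus bivittatus,181,,2,-9,548,14
Chautauqua,1752,Melanoplus dawsoni,186,,-5,-1,580,18
Chautauqua,1752,Hesperotettix viridis,186,,-3,-4,580,18
A1,2195,Aeropedellus clavatus,167,,-10,-3,190,
A1,2195,Melanoplus confusus,167,,8,-3,190,
A1,2195,Melanoplus dodgei,174,,-17,-16,240,
A1,2195,Melanoplus sanguinipes,183,,7,1,292,
A1,2195,Cratypedes neglectus,195,,-26,-19,386,
A1,2195,Camnula pellucida,195,,10,3,386,
A1,2195,Hesperotettix viridis,202,,-12,-4,433,
A1,2195,Melanoplus bivittatus,202,,3,-11,433,
A1,2195,Trimerotropis cincta,202,,3,-4,433,
B1,2591,Aeropedellus clavatus,172,-13,-17,-10,137,19
B1,2591,Melanoplus dodgei,172,-13,-17,-10,137,19
B1,2591,Camnula pellucida,202,-14,-5,-11,289,6
B1,2591,Circotettix rabula,207,-19,-10,-16,315,20
B1,2591,Melanoplus dawsoni,215,-27,-18,-8,367,6
B1,2591,Melanoplus packardii,216,-28,-26,-18,389,16
B1,2591,Chloealtis abdominalis,216,-21,-19,-18,389,16
C1,3048,Melanoplus dodgei,182,-10,-5,-3,61,1
C1,3048,Melanoplus fasciatus,202,-15,-3,-5,111,15
C1,3048,Camnula pellucida,209,-22,-10,-3,144,26
C1,3048,Chloealtis abdominalis,216,-16,-17,-10,159,26
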