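# Pairwise comparisons of the five resistance factors (Saaty 1-9 scale)
# order: landuse, vegcover, slope, dist_county_road, dist_highway
1    1/5  1/6  1/3  1/4
5    1    1/2  4    3
6    2    1    3    2
3    1/4  1/3  1    1/2
4    1/3  1/2  2    1
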