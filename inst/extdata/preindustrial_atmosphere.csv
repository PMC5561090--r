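year,ca_ppm,d13c_air_permil
1500,280,-6.4
1525,280,-6.4
1550,280,-6.4
1575,280,-6.4
1600,280,-6.4
1625,280,-6.4
1650,280,-6.4
1675,280,-6.4
1700,280,-6.4
1725,280,-6.4
1750,280,-6.4
1775,280,-6.4
1800,280,-6.4
1825,280,-6.4
1850,280,-6.4
1875,280,-6.4
1900,280,-6.4
1925,280,-6.4
1950,280,-6.4
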