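# Published per-SNP cohort report for the 52-sample retina dataset:
# integer columns (heterozygous samples, directional imbalance counts)
# and the printed percentages they imply. Used to check that the
# frequency arithmetic reproduces every printed row.
published_report <- function() {
  tibble::tribble(
    ~gene_snp,            ~n_het, ~n_below, ~n_above, ~n_imb, ~freq_het, ~freq_cohort,
    "ABCA4_rs1762114",        16,        0,        8,      8,      50.0,         15.4,
    "ABHD12_rs6107027",       20,       11,        1,     12,      60.0,         23.1,
    "BBS5_rs7589199",         11,        5,        3,      8,      72.7,         15.4,
    "BEST1_rs149698",         22,        1,        6,      7,      31.8,         13.5,
    "BEST1_rs1800009",        20,        4,        2,      6,      30.0,         11.5,
    "C3_rs17030",             29,        2,        6,      8,      27.6,         15.4,
    "CC2D2A_rs4698387",       17,       11,        0,     11,      64.7,         21.2,
    "CDHR1_rs4244947",        23,       21,        2,     23,     100.0,         44.2,
    "CDHR1_rs4933980",        21,       21,        0,     21,     100.0,         40.4,
    "CDHR1_rs10509491",       20,       11,        0,     11,      55.0,         21.2,
    "CDHR1_rs7895270",        16,       10,        0,     10,      62.5,         19.2,
    "CDHR1_rs2279229",        15,        7,        1,      8,      53.3,         15.4,
    "CNGB1_rs17821448",       30,        1,       10,     11,      36.7,         21.2,
    "COL11A1_rs2229783",      19,        2,        7,      9,      47.4,         17.3,
    "FLVCR1_rs10864027",      24,        5,        1,      6,      25.0,         11.5,
    "GRK1_rs9796035",         21,       10,        2,     12,      57.1,         23.1,
    "GRM6_rs11746675",        32,        5,        4,      9,      28.1,         17.3,
    "GRM6_rs2067011",         29,        4,        3,      7,      24.1,         13.5,
    "GRM6_rs2071246",         22,        2,        4,      6,      27.3,         11.5,
    "IDH3B_rs5026920",        12,        8,        0,      8,      66.7,         15.4,
    "INPP5E_rs1128874",       27,        8,        1,      9,      33.3,         17.3,
    "INPP5E_rs10870194",      24,        0,       24,     24,     100.0,         46.2,
    "INPP5E_rs35763810",      20,        0,        6,      6,      30.0,         11.5,
    "MYO7A_rs2276288",        17,       13,        1,     14,      82.4,         26.9,
    "PRCD_rs5742903",         25,        7,        2,      9,      36.0,         17.3,
    "PRCD_rs895157",          17,        6,        1,      7,      41.2,         13.5,
    "PROM1_rs3130",           20,        0,       19,     19,      95.0,         36.5,
    "PRPH2_rs425876",         14,        1,        7,      8,      57.1,         15.4,
    "RP1_rs61739567",         11,        0,        8,      8,      72.7,         15.4,
    "WFS1_rs1046319",         12,        0,        7,      7,      58.3,         13.5
  )
}
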