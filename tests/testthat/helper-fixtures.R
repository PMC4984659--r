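# fixtures are built in code; nothing is read from disk

catalog_row <- function(id, virus, group, rate, timescale,
                        block = virus, alt = "a1", genus = "") {
  data.frame(record_id = id, virus_name = virus, baltimore_group = group,
             genus = genus, rate = rate, timescale = timescale,
             block_id = block, alternative_id = alt,
             source_id = paste0("src_", id), stringsAsFactors = FALSE)
}

# one nested-independence block in the style of the herpesvirus example:
# three mutually exclusive alternatives of unequal size
herpes_block <- function(group = "I") {
  rbind(
    catalog_row("h1", "HSV1", group, 3e-4, 20, block = "herpes", alt = "species"),
    catalog_row("h2", "HSV1", group, 5e-4, 35, block = "herpes", alt = "species"),
    catalog_row("h3", "VZV", group, 2e-4, 40, block = "herpes", alt = "species"),
    catalog_row("h4", "alphaherpes", group, 5e-8, 8e6, block = "herpes",
                alt = "subfamily"),
    catalog_row("h5", "alphabetaherpes", group, 2e-8, 6e7, block = "herpes",
                alt = "family"),
    catalog_row("h6", "alphabetaherpes", group, 4e-8, 9e7, block = "herpes",
                alt = "family"))
}

# two-group toy catalog: group I carries the nested herpes block, group IV
# simple one-virus blocks; both groups have short and long records
toy_catalog <- function() {
  rate_dataset(rbind(
    herpes_block("I"),
    catalog_row("i1", "poxlike", "I", 1e-4, 100),
    catalog_row("i2", "ancient_pox", "I", 5e-8, 5e6),
    catalog_row("t1", "TMV", "IV", 1e-3, 15, genus = "Tobamovirus"),
    catalog_row("t2", "TMV", "IV", 8e-4, 30, genus = "Tobamovirus"),
    catalog_row("t3", "CMV", "IV", 2e-3, 8, genus = "Cucumovirus"),
    catalog_row("t4", "palm_virus", "IV", 3e-7, 2e5, genus = "Tobamovirus")),
    label = "toy")
}

# minimal catalog with zero sampling freedom: one alternative per block,
# one record per virus
fixed_catalog <- function() {
  rate_dataset(rbind(
    catalog_row("f1", "v1", "I", 1e-4, 10),
    catalog_row("f2", "v2", "I", 1e-7, 1e5),
    catalog_row("f3", "v3", "IV", 1e-3, 50),
    catalog_row("f4", "v4", "IV", 1e-6, 1e4)),
    label = "fixed")
}

# zero-noise catalog: every record exactly on its group's power-law line
exact_catalog <- function(slope = -0.65,
                          intercepts = c(I = -3.4, IV = -2.1)) {
  cfg <- synthetic_catalog_config(
    intercepts = intercepts, slope = slope, noise_sd = 0,
    n_short = c(I = 6L, IV = 6L), n_long = c(I = 2L, IV = 2L), seed = 11)
  generate_synthetic_catalog(cfg)
}

table1_catalog <- function(seed = 1) {
  generate_synthetic_catalog(table1_config(seed = seed))
}

# a six-taxon ladder time tree; the MRCA of A and B is the calibration
# node and every deeper node is a fixed multiple of its age
ladder_time_tree <- function(cal_age = 10500,
                             multiples = c(16, 8, 4, 2, 1)) {
  h <- cal_age * multiples  # root ... calibration node
  txt <- sprintf(
    "(((((A:%.12g,B:%.12g):%.12g,C:%.12g):%.12g,D:%.12g):%.12g,E:%.12g):%.12g,F:%.12g);",
    h[5], h[5], h[4] - h[5], h[4], h[3] - h[4], h[3], h[2] - h[3], h[2],
    h[1] - h[2], h[1])
  ape::read.tree(text = txt)
}

ladder_true_ages <- function(cal_age = 10500,
                             multiples = c(16, 8, 4, 2, 1)) {
  h <- cal_age * multiples
  c("A|B|C|D|E|F" = h[1], "A|B|C|D|E" = h[2], "A|B|C|D" = h[3],
    "A|B|C" = h[4], "A|B" = h[5])
}
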