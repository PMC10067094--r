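test_that("HGVS protein parsing handles the common dialects", {
  p <- parse_hgvs_p(c("R282W", "E298X", "p.E298*", "E298Ter", "R213fs",
                      "P72Rfs*5", "X187_splice", "P72=", "P72P",
                      "K120del"))
  expect_equal(p$effect,
               c("missense", "nonsense", "nonsense", "nonsense",
                 "frameshift", "frameshift", "splice", "synonymous",
                 "synonymous", "inframe_indel"))
  expect_equal(p$ref_residue[1], "R")
  expect_equal(p$position[1], 282L)
  expect_equal(p$alt_residue[1], "W")
  # stop-symbol dialects normalize to one internal representation
  expect_equal(p[2, -1], p[3, -1], ignore_attr = TRUE)
  expect_equal(p[2, -1], p[4, -1], ignore_attr = TRUE)
  expect_true(is.na(p$position[7]))  # splice has no protein position
})

test_that("unparseable strings raise errors naming the raw text", {
  expect_error(parse_hgvs_p("282RW"), "282RW")
  expect_error(parse_hgvs_p("B100W"), "nonstandard")
  expect_error(parse_hgvs_p(NA_character_), "cannot parse")
  # an explicit MAF class rescues a shapeless string
  expect_equal(parse_hgvs_p(NA_character_, "Splice_Site")$effect, "splice")
})

test_that("parse -> format -> parse is the identity on normalized forms", {
  changes <- c("R282W", "E298X", "p.Y220C", "R213fs", "X125_splice",
               "P72=", "R175H")
  p1 <- parse_hgvs_p(changes)
  p2 <- parse_hgvs_p(format_hgvs_p(p1))
  expect_equal(p1[, c("ref_residue", "position", "alt_residue", "effect")],
               p2[, c("ref_residue", "position", "alt_residue", "effect")])
})

test_that("annotation applies the disruptive and EAp53 rules", {
  ann <- annotate_simple(c("E298X", "R282W", "R249S", "Y236C", "R213fs",
                           "X187_splice"))
  # truncating variants are disruptive, EAp53 never applies
  expect_equal(ann$is_truncating,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(ann$is_disruptive[ann$is_truncating]))
  expect_true(all(ann$eap53_class[ann$is_truncating] == "not_applicable"))
  # R282W: exon 8, in DBD, outside L2/L3 -> nondisruptive
  expect_equal(ann$exon[2], 8L)
  expect_true(ann$in_dbd[2])
  expect_false(ann$in_l2_l3[2])
  expect_false(ann$is_disruptive[2])
  # R249S: in L3, positive -> polar-uncharged switch -> disruptive
  expect_true(ann$in_l2_l3[3])
  expect_true(ann$is_disruptive[3])
  # Y236C: in L3 but same polarity group -> nondisruptive
  expect_true(ann$in_l2_l3[4])
  expect_false(ann$is_disruptive[4])
})

test_that("EAp53 threshold is > 75 for high risk, missense only", {
  expect_equal(eap53_class(75.0, "missense"), "low_risk")
  expect_equal(eap53_class(75.01, "missense"), "high_risk")
  expect_equal(eap53_class(90, "nonsense"), "not_applicable")
  expect_equal(eap53_class(NA_real_, "missense"), "not_applicable")
  expect_error(eap53_class(101, "missense"), "\\[0, 100\\]")
  # supplied scores take precedence over the lookup table
  ann <- annotate_simple("R282W", ea_score = 40)
  expect_equal(ann$eap53_class, "low_risk")
  ann2 <- annotate_simple("R282W")  # bundled synthetic table: 93.2
  expect_equal(ann2$eap53_class, "high_risk")
})

test_that("missense beyond the protein length is an annotation error", {
  expect_error(annotate_simple("R394W"), "exceeds protein length")
})

test_that("every variant gets exactly one effect, one disruptive call and one EAp53 class", {
  set.seed(23)
  seq_chars <- strsplit(refset$sequence, "")[[1]]
  pos <- sample(393, 200, replace = TRUE)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  kinds <- sample(c("mis", "non", "fs"), 200, replace = TRUE)
  changes <- ifelse(kinds == "mis",
                    paste0(seq_chars[pos], pos, sample(aa, 200, TRUE)),
             ifelse(kinds == "non", paste0(seq_chars[pos], pos, "*"),
                    paste0(seq_chars[pos], pos, "fs")))
  ann <- annotate_simple(changes, ea_score = round(runif(200, 0, 100), 1))
  expect_true(all(ann$effect %in% c("missense", "nonsense", "frameshift",
                                    "synonymous")))
  expect_true(all(ann$eap53_class %in%
                    c("high_risk", "low_risk", "not_applicable")))
  expect_type(ann$is_disruptive, "logical")
  expect_false(anyNA(ann$is_disruptive))
  # subset law: truncating implies disruptive
  expect_true(all(ann$is_disruptive[ann$is_truncating]))
})

test_that("disruptive calls equal the brute-force rule over all 393 x 20 substitutions", {
  seq_chars <- strsplit(refset$sequence, "")[[1]]
  aa <- names(refset$properties)
  grid <- expand.grid(pos = 1:393, alt = aa, stringsAsFactors = FALSE)
  grid$ref <- seq_chars[grid$pos]
  grid <- grid[grid$ref != grid$alt, ]
  ann <- annotate_simple(paste0(grid$ref, grid$pos, grid$alt))
  oracle <- oracle_disruptive_missense(grid$ref, grid$pos, grid$alt)
  expect_equal(ann$is_disruptive, unname(oracle))
})
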