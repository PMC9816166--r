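test_that("LOH state is a total function matching the state table", {
  # independent statement of the classification table
  expected_state <- function(major, minor) {
    if (minor == 0) {
      if (major == 0) return("HOM_DEL")
      if (major == 1) return("LOH_LOSS")
      if (major == 2) return("CN_LOH")
      return("CG_LOH")
    }
    if (major >= 2) return("GAIN_NO_LOH")
    "NO_LOH"
  }
  for (major in 0:8) for (minor in 0:major) {
    expect_equal(loh_state(major, minor), expected_state(major, minor),
                 label = sprintf("state (%d,%d)", major, minor))
  }
})

test_that("whole-chromosome vs segmental boundary sits at 95% of the
           chromosome", {
  chrom_len <- 81195210
  locus <- tp53_locus()
  seg_at <- function(frac) {
    cn_segments(chrom = c("17", "17"),
                start = c(0, round(chrom_len * frac)),
                end = c(round(chrom_len * frac), chrom_len),
                major = c(2, 1), minor = c(0, 1))
  }
  above <- classify_locus(seg_at(0.96), locus, chrom_len)
  expect_equal(above$state, "CN_LOH")
  expect_equal(above$extent, "WHOLE_CHROMOSOME")
  below <- classify_locus(seg_at(0.94), locus, chrom_len)
  expect_equal(below$extent, "SEGMENTAL")
  # abutting same-state segments merge into one run
  split2 <- cn_segments(chrom = c("17", "17"), start = c(0, 4e7),
                        end = c(4e7, chrom_len), major = 2, minor = 0)
  expect_equal(classify_locus(split2, locus, chrom_len)$extent,
               "WHOLE_CHROMOSOME")
})

test_that("segmental copy-gain and diploid states classify per the table", {
  chrom_len <- 81195210
  locus <- tp53_locus()
  cg <- cn_segments(chrom = c("17", "17"), start = c(0, 1.2e7),
                    end = c(1.2e7, chrom_len), major = c(3, 1),
                    minor = c(0, 1))
  call <- classify_locus(cg, locus, chrom_len)
  expect_equal(call$state, "CG_LOH")
  expect_equal(call$extent, "SEGMENTAL")
  dip <- cn_segments("17", 0, chrom_len, 1, 1)
  expect_equal(classify_locus(dip, locus, chrom_len)$state, "NO_LOH")
  # no overlapping segment is fatal; subclonal coverage is flagged
  expect_error(classify_locus(dip[0, ], locus, chrom_len), "no copy")
  sub <- cn_segments("17", 0, chrom_len, 2, 0, clonal_fraction = 0.3)
  expect_true(classify_locus(sub, locus, chrom_len)$low_confidence)
})

test_that("mutant-allele assignment follows the two-population VAF
           accounting", {
  # purity 1, (2,0): only the major allele exists; VAF near 1 -> MAJOR
  a <- assign_mutant_allele(0.5, 39, 40, purity = 1, major = 2, minor = 0)
  expect_equal(a$call, "MAJOR")
  # purity 0.5, (2,0): expected VAF mutant-on-major = 0.75
  b <- assign_mutant_allele(0.5, 30, 40, purity = 0.5, major = 2,
                            minor = 0)
  expect_equal(unname(b$expected_vaf["MAJOR"]), 0.75)
  expect_equal(unname(b$expected_vaf["MINOR"]), 0.25)
  expect_equal(b$call, "MAJOR")
  # observed VAF near 1/3 with (2,1) at purity 1 favours mutant-on-minor
  cc <- assign_mutant_allele(0.5, 14, 40, purity = 1, major = 2,
                             minor = 1)
  ll_minor <- dbinom(14, 40, 1 / 3, log = TRUE)
  ll_major <- dbinom(14, 40, 2 / 3, log = TRUE)
  expect_equal(unname(cc$loglik), c(ll_major, ll_minor))
  expect_equal(cc$call, "MINOR")
  # an observation exactly between the hypotheses is a likelihood tie
  mid <- assign_mutant_allele(0.5, 20, 40, purity = 1, major = 2,
                              minor = 1)
  expect_equal(mid$call, "TIE")
})

test_that("mutant-allele assignment is antisymmetric and ties are
           surfaced", {
  x <- assign_mutant_allele(0.5, 28, 40, purity = 0.8, major = 2,
                            minor = 1)
  y <- assign_mutant_allele(0.5, 28, 40, purity = 0.8, major = 1,
                            minor = 2)
  # note: swapping (major, minor) swaps the hypotheses' copy numbers
  expect_equal(unname(x$expected_vaf["MAJOR"]),
               unname(y$expected_vaf["MINOR"]))
  expect_false(x$call == y$call)
  tie <- assign_mutant_allele(0.5, 20, 40, purity = 1, major = 2,
                              minor = 2)
  expect_equal(tie$call, "TIE")
  expect_true(tie$tie)
})

test_that("VAF-shift test equals hypergeometric enumeration", {
  cases <- list(c(25, 50, 49, 50), c(25, 50, 26, 50), c(10, 30, 25, 40))
  for (cs in cases) {
    p <- vaf_shift_test(cs[1], cs[2], cs[3], cs[4])
    p_enum <- fisher_enum(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3])
    expect_equal(p, p_enum, tolerance = 1e-9)
  }
  expect_equal(vaf_shift_test(25, 50, 25, 50), 1.0)
  expect_lt(vaf_shift_test(25, 50, 49, 50), 1e-6)
  expect_gt(vaf_shift_test(25, 50, 26, 50), 0.5)
  expect_error(vaf_shift_test(0, 0, 10, 20), "zero-depth")
})
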