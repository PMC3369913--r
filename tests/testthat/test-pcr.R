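test_that("degeneracy is the product of per-code cardinalities", {
  expect_equal(degeneracy("ACGT"), 1)
  expect_equal(degeneracy("ACN"), 4)
  expect_equal(degeneracy("CAAGCGGCAGCGGACNCSNTAYAC"), 64)  # Dfd forward
  expect_error(degeneracy("ACZ"), "illegal")
  # multiplicativity under concatenation
  set.seed(501)
  codes <- names(hoxrates:::IUPAC_SETS)
  for (i in 1:20) {
    a <- paste(sample(codes, 5, TRUE), collapse = "")
    b <- paste(sample(codes, 7, TRUE), collapse = "")
    expect_equal(degeneracy(paste0(a, b)), degeneracy(a) * degeneracy(b))
  }
})

test_that("IUPAC matching equals set membership for all 15 x 4 pairs", {
  sets <- hoxrates:::IUPAC_SETS
  for (code in names(sets)) {
    for (base in c("A", "C", "G", "T")) {
      expect_identical(iupac_match(code, base), base %in% sets[[code]])
    }
  }
  expect_true(iupac_match("N", "G"))
  expect_false(iupac_match("Y", "A"))
  expect_error(iupac_match("A", "N"), "ambiguous")
  expect_true(iupac_match("R", "N", ambiguous_template = "intersect"))
})

test_that("binding sites match a brute-force sliding-window oracle", {
  set.seed(502)
  oracle_sites <- function(template, primer_seq, max_mm) {
    tc <- strsplit(template, "")[[1]]
    pc <- strsplit(primer_seq, "")[[1]]
    hits <- integer(0)
    for (s in seq_len(length(tc) - length(pc) + 1L)) {
      mm <- sum(!mapply(iupac_match, pc, tc[s:(s + length(pc) - 1L)]))
      if (mm <= max_mm) hits <- c(hits, s - 1L)
    }
    hits
  }
  for (i in 1:15) {
    tmpl <- random_nt(120)
    prim <- paste(sample(c("A", "C", "G", "T", "N", "R", "Y"), 10, TRUE),
                  collapse = "")
    mm <- sample(0:2, 1)
    mine <- find_binding_sites(tmpl, degenerate_primer("p", prim, "forward"),
                               max_mismatch = mm)
    expect_identical(mine$start[mine$strand == "+"],
                     oracle_sites(tmpl, prim, mm))
  }
})

test_that("embedded expansions are found on the correct strands", {
  set.seed(503)
  fw <- degenerate_primer("fw", "ACGTNNRY", "forward")
  core <- sample_expansion(fw$sequence)
  tmpl <- paste0(random_nt(30), core, random_nt(30))
  hit <- find_binding_sites(tmpl, fw)
  expect_true(any(hit$start == 30 & hit$strand == "+"))
  # the same primer in reverse orientation finds the reverse complement
  rc_tmpl <- reverse_complement(tmpl)
  rv <- degenerate_primer("rv", fw$sequence, "reverse")
  hit2 <- find_binding_sites(rc_tmpl, rv)
  expect_true(any(hit2$strand == "-" & hit2$start == 30))
  # primer longer than template -> empty
  expect_equal(nrow(find_binding_sites("ACGT", fw)), 0L)
})

test_that("amplicons on constructed templates have the published lengths", {
  set.seed(504)
  prim <- load_primer_table()
  for (pair in unique(prim$pair)) {
    rows <- prim[prim$pair == pair, ]
    fw <- degenerate_primer(rows$name[rows$orientation == "forward"],
                            rows$sequence[rows$orientation == "forward"],
                            "forward")
    rv <- degenerate_primer(rows$name[rows$orientation == "reverse"],
                            rows$sequence[rows$orientation == "reverse"],
                            "reverse")
    want <- rows$expected_fragment_bp[1]
    gap <- want - nchar(fw$sequence) - nchar(rv$sequence)
    tmpl <- paste0(random_nt(25), sample_expansion(fw$sequence),
                   random_nt(gap),
                   sample_expansion(reverse_complement(rv$sequence)),
                   random_nt(25))
    amp <- predict_amplicons(tmpl, fw, rv)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$product_length, want)
  }
})

test_that("no reverse site means no product; size filters apply", {
  set.seed(505)
  fw <- degenerate_primer("fw", "ACGTACGTAC", "forward")
  tmpl <- paste0(random_nt(10), "ACGTACGTAC", random_nt(50))
  rv <- degenerate_primer("rv", "GGGGGGGGGG", "reverse")
  expect_equal(nrow(predict_amplicons(tmpl, fw, rv)), 0L)
  # all fw x rev combinations within range are enumerated
  core_rv <- reverse_complement("TTTTAAAACC")
  rv2 <- degenerate_primer("rv2", "TTTTAAAACC", "reverse")
  tmpl2 <- paste0("ACGTACGTAC", random_nt(5), core_rv, random_nt(5), core_rv)
  amp <- predict_amplicons(tmpl2, fw, rv2)
  expect_equal(nrow(amp), 2L)
  expect_equal(sort(amp$product_length), c(25, 40))
  expect_equal(nrow(predict_amplicons(tmpl2, fw, rv2,
                                      size_range = c(30, 50))), 1L)
})

test_that("product length is invariant under reverse-complement role swap", {
  set.seed(506)
  fw <- degenerate_primer("fw", "ACGGTNACRT", "forward")
  rv <- degenerate_primer("rv", "CCYTAGGTNA", "reverse")
  tmpl <- paste0(random_nt(15), sample_expansion(fw$sequence), random_nt(40),
                 sample_expansion(reverse_complement(rv$sequence)),
                 random_nt(15))
  a <- predict_amplicons(tmpl, fw, rv)
  swapped_fw <- degenerate_primer("fw2", rv$sequence, "forward")
  swapped_rv <- degenerate_primer("rv2", fw$sequence, "reverse")
  b <- predict_amplicons(reverse_complement(tmpl), swapped_fw, swapped_rv)
  expect_equal(nrow(a), 1L)
  expect_equal(a$product_length, b$product_length)
})

test_that("Wallace-rule Tm ranges span the GC expansions", {
  expect_equal(unname(melting_temperature_range("AAAA")), c(8, 8))
  expect_equal(unname(melting_temperature_range("GGGG")), c(16, 16))
  expect_equal(unname(melting_temperature_range("AN")), c(4, 6))
  expect_equal(unname(melting_temperature_range("SW")), c(6, 6))
  # range bounds bracket every concrete expansion's Tm
  tm_plain <- function(s) {
    v <- strsplit(s, "")[[1]]
    2 * sum(v %in% c("A", "T")) + 4 * sum(v %in% c("G", "C"))
  }
  set.seed(507)
  rng <- melting_temperature_range("CARYSNTW")
  for (i in 1:20) {
    tm <- tm_plain(sample_expansion("CARYSNTW"))
    expect_gte(tm, rng[["min"]]); expect_lte(tm, rng[["max"]])
  }
})
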