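# Curation-filter boundary cases and Rost-curve redundancy clustering.

# A complex with tunable segment: chain A of `n` residues (optionally with
# `n_ss` designed disulfides), chain B a 100-residue partner far away.
filter_fixture <- function(n, n_ss = 0L) {
  a <- make_chain("extended", n = n, chain_id = "A")$atoms
  if (n_ss > 0) {
    for (k in seq_len(n_ss)) {
      base <- c(k * 12, 15, 0)
      c1 <- build_residue("CYS", chain_id = "A", resno_start = 1000L + 2 * k)
      c1 <- idrg:::.orient_residue(c1, "SG", base, "CB", c(0, 0, 1))
      c2 <- build_residue("CYS", chain_id = "A", resno_start = 1001L + 2 * k)
      c2 <- idrg:::.orient_residue(c2, "SG", base + c(2.04, 0, 0), "CB",
                                   c(0, 0, 1))
      a <- rbind(a, c1, c2)
    }
  }
  b <- make_chain("globule", n = 100, chain_id = "B")$atoms
  b$y <- b$y + 80
  model_from_atoms(rbind(a, b), id = "filter_fixture")
}

test_that("length and disulfide gates reproduce the boundary cases", {
  # 18 observed residues: too short
  fr <- apply_structure_filters(filter_fixture(18))
  a <- fr[fr$chain == "A", ]
  expect_false(a$pass)
  expect_match(a$failed_rules, "min_segment_len")
  # 60-residue chain with 3 disulfides: disulfide-rich, excluded
  # (the designed CYS pairs add 6 residues: 66 observed, still < 100)
  fr2 <- apply_structure_filters(filter_fixture(60, n_ss = 3L))
  a2 <- fr2[fr2$chain == "A", ]
  expect_equal(a2$n_disulfides, 3L)
  expect_false(a2$pass)
  expect_match(a2$failed_rules, "disulfide_rich")
  # 150-residue chain with 4 disulfides: long enough to keep
  fr3 <- apply_structure_filters(filter_fixture(150, n_ss = 4L))
  a3 <- fr3[fr3$chain == "A", ]
  expect_equal(a3$n_disulfides, 4L)
  expect_true(a3$pass)
  # a clean mid-length chain passes
  fr4 <- apply_structure_filters(filter_fixture(40))
  expect_true(fr4[fr4$chain == "A", "pass"])
})

test_that("the partner-length gate requires some chain above 70 residues", {
  a <- make_chain("extended", n = 40, chain_id = "A")$atoms
  b <- make_chain("globule", n = 50, chain_id = "B")$atoms
  b$y <- b$y + 80
  m <- model_from_atoms(rbind(a, b), id = "small_partner")
  fr <- apply_structure_filters(m)
  expect_false(any(fr$pass))
  expect_true(all(grepl("min_partner_len", fr$failed_rules)))
})

test_that("external exclusion lists remove chains by id", {
  m <- filter_fixture(40)
  fr <- apply_structure_filters(m, external_exclusions = "filter_fixture:A")
  expect_false(fr[fr$chain == "A", "pass"])
  expect_match(fr[fr$chain == "A", "failed_rules"], "external_exclusion")
  # the exclusion names only the listed chain
  expect_no_match(fr[fr$chain == "B", "failed_rules"], "external_exclusion")
})

test_that("filter outcomes are order-independent and reproducible", {
  m <- filter_fixture(60, n_ss = 3L)
  expect_identical(apply_structure_filters(m), apply_structure_filters(m))
})

test_that("the Rost curve caps at 100, decays to its offset, and matches direct evaluation", {
  expect_equal(rost_threshold(1, 3), 100)
  # the curve decays (slowly, as L^-0.32) towards the offset n
  expect_equal(rost_threshold(1e30, 3), 3, tolerance = 1e-6)
  expect_gt(rost_threshold(1e4, 3), 3)
  # direct evaluation of the stated curve at L = 250, n = 3
  L <- 250
  expect_equal(rost_threshold(L, 3),
               3 + 480 * L^(-0.32 * (1 + exp(-L / 1000))), tolerance = 1e-12)
  # steeply decreasing through the short-alignment regime (the exponential
  # length correction makes the stated form shallow and slightly
  # non-monotone beyond L ~ 400)
  expect_true(all(diff(rost_threshold(seq(20, 400, by = 10), 3)) < 0))
  expect_lt(rost_threshold(400, 3), rost_threshold(50, 3))
  expect_error(rost_threshold(0), ">= 1")
})

test_that("redundancy clustering joins homologs and keeps the best representative", {
  ids <- c("s1", "s2", "s3")
  idm <- matrix(c(100, 90, 10,
                  90, 100, 12,
                  10, 12, 100), 3, 3, dimnames = list(ids, ids))
  len <- matrix(200, 3, 3, dimnames = list(ids, ids))
  # 90% identity over L=200 far exceeds the Rost threshold (~26%): clustered
  expect_gt(90, rost_threshold(200, 3))
  expect_lt(12, rost_threshold(200, 3))
  cl <- redundancy_cluster(idm, len,
                           resolution = c(s1 = 2.5, s2 = 1.8, s3 = 2.0),
                           chain_len = c(s1 = 200, s2 = 200, s3 = 200))
  expect_equal(sort(cl$representatives), c("s2", "s3"))
  expect_equal(unname(cl$component[c("s1", "s2")]),
               rep(cl$component[["s1"]], 2))
  # representative set is an independent set; excluded chains are connected
  # to their representative's component
  expect_equal(nrow(cl$edges), 1L)
  # determinism
  cl2 <- redundancy_cluster(idm, len,
                            resolution = c(s1 = 2.5, s2 = 1.8, s3 = 2.0),
                            chain_len = c(s1 = 200, s2 = 200, s3 = 200))
  expect_identical(cl$representatives, cl2$representatives)
  # ties on resolution: longest chain wins, then lexicographic id
  cl3 <- redundancy_cluster(idm, len, resolution = c(s1 = 2, s2 = 2, s3 = 2),
                            chain_len = c(s1 = 250, s2 = 200, s3 = 200))
  expect_true("s1" %in% cl3$representatives)
})

test_that("pairwise identity via global alignment feeds the clustering", {
  skip_if_not_installed("Biostrings")
  seqs <- c(a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            b = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            c = "WWGGPPLLNNHHEEDDKKRRSSTTVVIIAAMMFF")
  pi_ <- pairwise_identity(seqs)
  expect_equal(pi_$identity[1, 2], 100, tolerance = 1e-9)
  expect_true(pi_$identity[1, 3] < 40)
  expect_true(isSymmetric(pi_$identity))
  cl <- redundancy_cluster(pi_$identity, pi_$length)
  expect_equal(length(cl$representatives), 2L)
})
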