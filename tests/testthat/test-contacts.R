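test_that("salt-bridge detection applies the strict 4.0 A rule", {
  m39 <- bridge_pair_model(3.9)
  sb <- find_salt_bridges(partition_complex(m39, "A"))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$donor_atom, "NZ")
  expect_equal(sb$acceptor_atom, "OE1")
  expect_equal(sb$distance, 3.9, tolerance = 1e-6)
  m405 <- bridge_pair_model(4.05)
  expect_equal(nrow(find_salt_bridges(partition_complex(m405, "A"))), 0L)
  # at exactly the cutoff: excluded (strict <)
  m400 <- bridge_pair_model(4.0)
  expect_equal(nrow(find_salt_bridges(partition_complex(m400, "A"))), 0L)
})

test_that("an ARG facing a carboxylate yields all close atom pairs", {
  arg <- build_residue("ARG", chain_id = "A")
  arg <- idrg:::.orient_residue(arg, "CZ", c(0, 0, 0), "NE", c(-1, 0, 0))
  glu <- build_residue("GLU", chain_id = "B")
  glu <- idrg:::.orient_residue(glu, "CD", c(3.9, 0, 0), "OE1", c(-0.4, 1, 0))
  m <- model_from_atoms(rbind(arg, glu), id = "arg_glu")
  sb <- find_salt_bridges(partition_complex(m, "A"), include_termini = FALSE)
  # oracle: brute-force all donor-N x acceptor-O distances
  dn <- arg[arg$elety %in% c("NE", "NH1", "NH2"), c("x", "y", "z")]
  ac <- glu[glu$elety %in% c("OE1", "OE2"), c("x", "y", "z")]
  cnt <- sum(sqrt(outer(rowSums(dn^2), rowSums(ac^2), `+`) -
                  2 * as.matrix(dn) %*% t(as.matrix(ac))) < 4.0)
  expect_equal(nrow(sb), cnt)
  expect_gte(nrow(sb), 2L)   # both guanidinium N see the carboxylate
})

test_that("terminal charged groups participate when enabled", {
  # N-terminal amide N of chain A near a C-terminal carboxylate of chain B
  gly_a <- build_residue("GLY", chain_id = "A")
  gly_a <- idrg:::.orient_residue(gly_a, "N", c(0, 0, 0), "CA", c(-1, 0, 0))
  gly_b <- build_peptide("GLY", chain_id = "B", oxt = TRUE)
  gly_b <- idrg:::.orient_residue(gly_b, "OXT", c(3.2, 0, 0), "C", c(1, 0, 0))
  m <- model_from_atoms(rbind(gly_a, gly_b), id = "termini")
  p <- partition_complex(m, "A")
  sb <- find_salt_bridges(p, include_termini = TRUE)
  expect_gte(nrow(sb), 1L)
  expect_true(any(sb$donor_atom == "N" & sb$acceptor_atom %in% c("O", "OXT")))
  expect_equal(nrow(find_salt_bridges(p, include_termini = FALSE)), 0L)
})

test_that("histidine donors are configurable", {
  his <- build_residue("HIS", chain_id = "A")
  his <- idrg:::.orient_residue(his, "NE2", c(0, 0, 0), "CD2", c(-1, 0, 0))
  asp <- build_residue("ASP", chain_id = "B")
  asp <- idrg:::.orient_residue(asp, "OD1", c(3.0, 0, 0), "CG", c(1, 0, 0))
  m <- model_from_atoms(rbind(his, asp), id = "his_asp")
  p <- partition_complex(m, "A")
  with_his <- find_salt_bridges(p, include_his = TRUE, include_termini = FALSE)
  expect_gte(nrow(with_his), 1L)
  expect_equal(nrow(find_salt_bridges(p, include_his = FALSE,
                                      include_termini = FALSE)), 0L)
})

test_that("hydrogen bonds obey the distance and angle criteria", {
  # backbone N-H...O=C at d_DA = 2.9 A, near-linear geometry
  don <- build_peptide(c("ALA", "ALA"), chain_id = "A")
  acc <- build_peptide("GLY", chain_id = "B")
  # place acceptor O of chain B 2.9 A from donor N of residue 2 of chain A,
  # roughly along the N-H direction (outward from the backbone)
  npos <- unlist(don[don$resno == 2 & don$elety == "N", c("x", "y", "z")])
  capos <- unlist(don[don$resno == 2 & don$elety == "CA", c("x", "y", "z")])
  cprev <- unlist(don[don$resno == 1 & don$elety == "C", c("x", "y", "z")])
  hdir <- (npos - capos) / sqrt(sum((npos - capos)^2)) +
    (npos - cprev) / sqrt(sum((npos - cprev)^2))
  hdir <- hdir / sqrt(sum(hdir^2))
  acc <- idrg:::.orient_residue(acc, "O", npos + 2.9 * hdir, "C", hdir)
  m <- model_from_atoms(rbind(don, acc), id = "hb")
  hb <- find_hbonds(partition_complex(m, "A"))
  expect_gte(nrow(hb), 1L)
  expect_true(any(hb$donor_atom == "N" & hb$acceptor_atom == "O" &
                    abs(hb$d_da - 2.9) < 1e-6))
  # same geometry stretched to 4.2 A: rejected
  acc2 <- idrg:::.orient_residue(acc, "O", npos + 4.2 * hdir, "C", hdir)
  m2 <- model_from_atoms(rbind(don, acc2), id = "hb_far")
  hb2 <- find_hbonds(partition_complex(m2, "A"))
  expect_false(any(hb2$donor_atom == "N" & hb2$acceptor_atom == "O" &
                     hb2$d_da > 4))
})

test_that("grid-based contact search equals brute-force enumeration", {
  set.seed(5)
  # a dense random soup of charged and polar residues on two chains
  res_pool <- c("LYS", "GLU", "ARG", "ASP", "SER", "GLN", "HIS", "GLY")
  build_soup <- function(chain, n, offset) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      r <- build_residue(sample(res_pool, 1), chain_id = chain,
                         resno_start = i)
      at <- c(runif(1, -8, 8), runif(1, -8, 8), offset + runif(1, -4, 4))
      idrg:::.orient_residue(r, "CA", at)
    }))
  }
  m <- model_from_atoms(rbind(build_soup("A", 14, 0), build_soup("B", 14, 5)),
                        id = "soup")
  p <- partition_complex(m, "A")
  expect_lte(nrow(m$atoms), 500)
  sb_g <- find_salt_bridges(p, method = "grid")
  sb_b <- find_salt_bridges(p, method = "brute")
  key <- function(df) sort(paste(df$donor_chain, df$donor_resno, df$donor_atom,
                                 df$acceptor_chain, df$acceptor_resno,
                                 df$acceptor_atom, round(df$distance, 9)))
  expect_equal(key(sb_g), key(sb_b))
  hb_g <- find_hbonds(p, method = "grid")
  hb_b <- find_hbonds(p, method = "brute")
  key2 <- function(df) sort(paste(df$donor_chain, df$donor_resno,
                                  df$donor_atom, df$acceptor_chain,
                                  df$acceptor_resno, df$acceptor_atom,
                                  round(df$d_da, 9)))
  expect_equal(key2(hb_g), key2(hb_b))
  expect_gt(nrow(sb_b) + nrow(hb_b), 0)   # the soup is dense enough to bond
})

test_that("contact counts are invariant under rigid transformation", {
  m <- make_toy_complex()
  p0 <- partition_complex(m, "A")
  n_sb <- nrow(find_salt_bridges(p0))
  n_hb <- nrow(find_hbonds(p0))
  for (s in 1:3) {
    mt <- transform_model(m, 100 + s)
    pt <- partition_complex(mt, "A")
    expect_equal(nrow(find_salt_bridges(pt)), n_sb)
    expect_equal(nrow(find_hbonds(pt)), n_hb)
  }
})

test_that("salt-bridge residues are themselves interface residues", {
  m <- make_toy_complex()
  p <- partition_complex(m, "A")
  sb <- find_salt_bridges(p)
  im <- interface_map(p)
  r <- im$residues
  for (k in seq_len(nrow(sb))) {
    don <- r[r$chain == sb$donor_chain[k] & r$resno == sb$donor_resno[k], ]
    acc <- r[r$chain == sb$acceptor_chain[k] &
               r$resno == sb$acceptor_resno[k], ]
    expect_gt(don$dsasa, 0.1)
    expect_gt(acc$dsasa, 0.1)
  }
})

test_that("disulfide detection pairs each SG at most once, greedily", {
  mk_cys <- function(resno, at) {
    r <- build_residue("CYS", chain_id = "A", resno_start = resno)
    idrg:::.orient_residue(r, "SG", at, "CB", c(0, 0, 1))
  }
  # canonical bond
  m <- model_from_atoms(rbind(mk_cys(1, c(0, 0, 0)), mk_cys(2, c(2.04, 0, 0))),
                        id = "ss")
  ss <- find_disulfides(m)
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$distance, 2.04, tolerance = 1e-6)
  # too far
  m2 <- model_from_atoms(rbind(mk_cys(1, c(0, 0, 0)), mk_cys(2, c(3.5, 0, 0))),
                         id = "ss_far")
  expect_equal(nrow(find_disulfides(m2)), 0L)
  # three clustered CYS: only the nearest pair bonds
  m3 <- model_from_atoms(rbind(mk_cys(1, c(0, 0, 0)),
                               mk_cys(2, c(2.0, 0, 0)),
                               mk_cys(3, c(-2.3, 0, 0))), id = "ss3")
  ss3 <- find_disulfides(m3)
  expect_equal(nrow(ss3), 1L)
  expect_setequal(c(ss3$resno1, ss3$resno2), c(1L, 2L))
})

test_that("contact summaries normalise per 100 A^2 and guard zero areas", {
  sb <- data.frame(distance = numeric(6))
  hb <- data.frame(d_da = numeric(12))
  cs <- summarize_contacts(sb, hb, 1250)
  expect_equal(cs$salt_bridges_per_100A2, 0.48)
  expect_equal(summarize_contacts(sb, hb, 1411.1)$hbonds_per_100A2, 0.8504,
               tolerance = 1e-4)
  cs0 <- summarize_contacts(sb[0, , drop = FALSE], hb[0, , drop = FALSE], 0)
  expect_equal(cs0$n_salt_bridges + cs0$n_hbonds, 0L)
  expect_error(summarize_contacts(sb, hb, 0), "zero interface")
})
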