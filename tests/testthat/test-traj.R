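test_that("dRMS is zero for identical frames and under rigid-body motion", {
  b <- gen_helical_bundle(n_chains = 2, n_frames = 3, jitter_sd_nm = 0,
                          seed = 1)
  xyz <- b$xyz
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz[2, , ] <- xyz[2, , ] %*% R + 1.5   # rotation + translation
  b2 <- traj_ensemble(b$atoms, xyz)
  d <- drms_series(b2, resno = 310:350)
  expect_equal(d$drms_nm, rep(0, 3), tolerance = 1e-12)
  expect_false(any(d$unstable))
})

test_that("dRMS matches the single-pair formula and flags instability", {
  tt <- two_atom_traj(1.0, 1.5)
  d <- drms_series(tt, resno = 1:10)
  expect_equal(d$drms_nm, c(0, 0.5))
  d2 <- drms_series(two_atom_traj(1.0, 2.5), resno = 1:10)
  expect_true(d2$unstable[2])   # dRMS 1.5 nm > 1 nm criterion
})

test_that("contact map equals the brute-force pairwise oracle", {
  set.seed(42)
  for (rep in 1:3) {
    nat <- c(50, 120, 200)[rep]
    at <- data.frame(chain = sample(c("A", "B"), nat, TRUE),
                     resno = sample(310:340, nat, TRUE),
                     resname = "ALA", name = "CA", element = "C")
    x <- array(runif(nat * 3, 0, 2.5), c(1, nat, 3))
    tr <- traj_ensemble(at, x)
    cm <- contact_map(tr, mode = "both")
    resnos <- sort(unique(at$resno))
    oracle <- matrix(0, length(resnos), length(resnos),
                     dimnames = list(resnos, resnos))
    for (i in 1:(nat - 1)) for (j in (i + 1):nat) {
      dd <- sqrt(sum((x[1, i, ] - x[1, j, ])^2))
      ri <- at$resno[i]; rj <- at$resno[j]
      same_res <- at$chain[i] == at$chain[j] && ri == rj
      elig <- !same_res && (at$chain[i] != at$chain[j] || abs(ri - rj) > 3)
      if (elig && dd < 0.6) {
        oracle[as.character(ri), as.character(rj)] <- 1
        oracle[as.character(rj), as.character(ri)] <- 1
      }
    }
    expect_identical(strip_map(cm), strip_map(oracle))
  }
})

test_that("contact cutoff and separation rules behave at the boundaries", {
  at <- data.frame(chain = c("A", "B"), resno = c(320, 330),
                   resname = "ALA", name = "CA", element = "C")
  mk <- function(d) {
    x <- array(0, c(1, 2, 3)); x[1, 2, 1] <- d
    contact_map(traj_ensemble(at, x), mode = "inter")
  }
  expect_equal(mk(0.59)["320", "330"], 1)   # inside the 0.6 nm cutoff
  expect_equal(mk(0.61)["320", "330"], 0)   # outside
  # |i-j| = 3 within one chain is excluded regardless of distance
  at2 <- data.frame(chain = "A", resno = c(320, 323), resname = "ALA",
                    name = "CA", element = "C")
  x2 <- array(0, c(1, 2, 3)); x2[1, 2, 1] <- 0.3
  cm2 <- contact_map(traj_ensemble(at2, x2), mode = "both")
  expect_equal(cm2["320", "323"], 0)
  # inter-chain pairs are always eligible at small separation
  at3 <- data.frame(chain = c("A", "B"), resno = c(320, 321),
                    resname = "ALA", name = "CA", element = "C")
  cm3 <- contact_map(traj_ensemble(at3, x2), mode = "inter")
  expect_equal(cm3["320", "321"], 1)
})

test_that("contact totals average with the right SEM", {
  at <- data.frame(chain = c("A", "B"), resno = c(320, 330),
                   resname = "ALA", name = "CA", element = "C")
  mk_map <- function(d) {
    x <- array(0, c(1, 2, 3)); x[1, 2, 1] <- d
    contact_map(traj_ensemble(at, x), mode = "inter")
  }
  m1 <- mk_map(0.3)   # in contact: N_contact = 1 for both residues
  # single pair at probability 1
  expect_equal(unname(rowSums(unclass(m1))), c(1, 1))
  # identical replicas -> SEM 0
  t0 <- contact_totals(list(m1, m1))
  expect_equal(t0$sem, c(0, 0))
  # replicas with totals 1 and 2 -> mean 1.5, SEM 0.5
  m2 <- unclass(m1); m2[] <- m2 * 2
  m2 <- structure(m2, class = class(m1), resno = attr(m1, "resno"))
  tt <- contact_totals(list(m1, m2))
  expect_equal(tt$n_contact, c(1.5, 1.5))
  expect_equal(tt$sem, c(0.5, 0.5))
  expect_error(contact_totals(list(m1)), ">= 2")
})

test_that("block averaging splits a run into equal contiguous maps", {
  b <- gen_helical_bundle(n_chains = 2, n_frames = 20, jitter_sd_nm = 0.02,
                          seed = 8)
  blocks <- contact_blocks(b, n_blocks = 5, mode = "inter")
  expect_length(blocks, 5)
  tot <- contact_totals(blocks)
  expect_true(all(tot$n_contact >= 0))
  expect_true(all(is.finite(tot$sem)))
})

test_that("minimum inter-chain distance matches a brute-force oracle", {
  b <- gen_helical_bundle(n_chains = 2, n_frames = 2, jitter_sd_nm = 0.01,
                          seed = 4)
  md <- min_interchain_distance(b, c("A", "B"))
  i1 <- select_atoms(b, chains = "A"); i2 <- select_atoms(b, chains = "B")
  oracle <- min(apply(expand.grid(i1, i2), 1, function(ij)
    sqrt(sum((b$xyz[1, ij[1], ] - b$xyz[1, ij[2], ])^2))))
  expect_equal(md$min_dist_nm[1], oracle, tolerance = 1e-12)
  # chains sharing an atom position -> 0
  at <- data.frame(chain = c("A", "B"), resno = 1, resname = "ALA",
                   name = "CA", element = "C")
  x <- array(0, c(1, 2, 3))
  expect_equal(min_interchain_distance(traj_ensemble(at, x),
                                       c("A", "B"))$min_dist_nm, 0)
  expect_error(min_interchain_distance(b, c("A", "Z")), "absent")
})

test_that("scripted dissociation episodes are recovered", {
  b <- gen_helical_bundle(n_chains = 2, n_frames = 12, jitter_sd_nm = 0.01,
                          dissociation = list(chain = "B", start = 5,
                                              end = 8, distance_nm = 4),
                          seed = 6)
  md <- min_interchain_distance(b, c("A", "B"), threshold = 0.6,
                                min_dwell = 2)
  ep <- attr(md, "episodes")
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start, ep$end), c(5, 8))
})

test_that("model confidence score is the stated linear combination", {
  expect_equal(af2_confidence(0.5, 0.5), 0.5)
  expect_equal(af2_confidence(1, 0), 0.8)
  expect_equal(af2_confidence(0.2, 0.7), 0.30)
  expect_error(af2_confidence(1.2, 0), "\\[0, 1\\]")
})
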