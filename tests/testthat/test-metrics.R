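test_that("reversal calls are opposite-signed with inclusive magnitude", {
  expect_true(is_reversed(-0.10, 1))
  expect_false(is_reversed(-0.05, 1))
  expect_false(is_reversed(0.5, 1))
  expect_true(is_reversed(0.10, -1))
  expect_false(is_reversed(0, 1))
  expect_false(is_reversed(0, -1))
})

test_that("motive impact counts match a brute-force recount", {
  motive <- list(name = "m", role = "response",
                 effectors = data.frame(
                   protein = paste0("E", 1:4),
                   sign = c(1L, 1L, 1L, -1L)))
  prof <- c(E1 = -0.5, E2 = -0.2, E3 = 0.05, E4 = 0.3)
  imp <- motive_impact(prof, motive)
  expect_equal(imp$n_eff, 3)
  expect_equal(imp$n_anti, 0)
  expect_equal(imp$pct_reversed, 75)

  zero <- motive_impact(setNames(rep(0, 4), paste0("E", 1:4)), motive)
  expect_equal(c(zero$n_eff, zero$n_anti, zero$pct_reversed), c(0, 0, 0))

  # randomised property: counts equal an independent elementwise recount
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    m <- list(name = "m", role = "response",
              effectors = data.frame(protein = paste0("P", 1:k),
                                     sign = sample(c(-1L, 1L), k, TRUE)))
    a <- setNames(round(runif(k, -1, 1), 3), paste0("P", 1:k))
    imp <- motive_impact(a, m)
    n_eff <- 0; n_anti <- 0
    for (i in 1:k) {
      if (abs(a[i]) >= 0.1 && sign(a[i]) == -m$effectors$sign[i])
        n_eff <- n_eff + 1
      if (abs(a[i]) >= 0.1 && sign(a[i]) == m$effectors$sign[i])
        n_anti <- n_anti + 1
    }
    expect_equal(imp$n_eff, n_eff)
    expect_equal(imp$n_anti, n_anti)
    expect_lte(imp$n_eff + imp$n_anti, imp$bed_p)
    expect_equal(imp$pct_reversed, 100 * n_eff / k)
  }
})

test_that("T-Signal is the mean signed reversion and is odd", {
  motive <- list(name = "m", role = "response",
                 effectors = data.frame(protein = "E1", sign = 1L))
  expect_equal(t_signal(c(E1 = -0.6), motive), 0.6)
  expect_equal(t_signal(c(E1 = 0), motive), 0)
  m2 <- list(name = "m", role = "response",
             effectors = data.frame(protein = c("A", "B"),
                                    sign = c(1L, -1L)))
  prof <- c(A = 0.3, B = -0.8)
  expect_equal(t_signal(-prof, m2), -t_signal(prof, m2))
})

test_that("W-Signal evaluates its formula and is monotone in the counts", {
  expect_equal(w_signal(3, 1, 4, 0.2), 1.7)
  expect_equal(w_signal(0, 2, 4, 0.35), 0.35)
  expect_equal(w_signal(4, 0, 4, 1), 6)
  # strictly increasing in n_eff, strictly decreasing in n_anti
  for (bed in c(5, 10)) {
    for (n_anti in 0:2) {
      vals <- vapply(0:(bed - n_anti), w_signal, numeric(1),
                     n_anti = n_anti, bed_p = bed, t_signal = 0.1)
      expect_true(all(diff(vals) > 0))
    }
    for (n_eff in 1:3) {
      vals <- vapply(0:(bed - n_eff), function(na)
        w_signal(n_eff, na, bed, 0.1), numeric(1))
      expect_true(all(diff(vals) < 0))
    }
  }
})

test_that("combination stimuli union targets and reject conflicts", {
  dxm <- drug_profile("DXM", data.frame(protein = c("NR3C1", "NR0B1"),
                                        sign = c(1L, 1L)))
  tcz <- drug_profile("TCZ", data.frame(protein = "IL6RA", sign = -1L))
  st <- combination_stimulus(dxm, tcz)
  expect_equal(st$clamped, c(NR3C1 = 1, NR0B1 = 1, IL6RA = -1))
  # idempotent with itself
  st2 <- combination_stimulus(dxm, dxm)
  expect_equal(st2$clamped, c(NR3C1 = 1, NR0B1 = 1))
  # conflicting shared target
  anti <- drug_profile("X", data.frame(protein = "NR3C1", sign = -1L))
  expect_error(combination_stimulus(dxm, anti), "conflicting")
})

test_that("synergy calls require the combination to beat both drugs", {
  expect_equal(assess_synergy(1.0, 1.2, 2.0)$label, "synergistic")
  expect_equal(assess_synergy(1.0, 1.2, 1.2)$label,
               "additive-or-sub-additive")
  expect_equal(assess_synergy(0, 0, 0)$label, "additive-or-sub-additive")
  # symmetric in the two single-drug scores
  set.seed(5)
  for (rep in 1:10) {
    v <- runif(3, -1, 3)
    expect_equal(assess_synergy(v[1], v[2], v[3])$label,
                 assess_synergy(v[2], v[1], v[3])$label)
  }
})

test_that("modulation classes follow the |0.3| threshold rules", {
  expect_equal(modulation_class(-0.6, -0.55), "both")
  expect_equal(modulation_class(-0.6, 0.0), "drug_a")
  expect_equal(modulation_class(0.0, -0.6), "drug_b")
  expect_equal(modulation_class(0.1, -0.1), "neither")
  expect_equal(modulation_class(0.9, 0.4), "drug_a")   # both on, far apart
  expect_equal(modulation_class(0.4, 0.9), "drug_b")
  expect_equal(modulation_class(c(-0.6, 0.1), c(-0.55, -0.1)),
               c("both", "neither"))
})

test_that("the effector table reports activities, signs and classes", {
  char <- disease_characterization(list(
    list(name = "m1", role = "response",
         effectors = data.frame(protein = c("A", "B"), sign = c(1L, -1L))),
    list(name = "m2", role = "basal",
         effectors = data.frame(protein = c("B", "C"), sign = c(-1L, 1L)))))
  pa <- c(A = -0.6, B = 0.2, C = 0.0)
  pb <- c(A = -0.5, B = 0.9, C = 0.0)
  tab <- effector_heatmap_table(pa, pb, char)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$motives[tab$protein == "B"], "m1;m2")
  expect_equal(tab$modulation[tab$protein == "A"], "both")
  expect_equal(tab$modulation[tab$protein == "B"], "drug_b")
  expect_equal(tab$disease_sign[tab$protein == "C"], 1L)
})
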