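test_that("identical individuals saturate the inclusion curve", {
  set.seed(71)
  base <- data.frame(x = rnorm(80, 0, 2), y = rnorm(80, 0, 2))
  loc_sets <- setNames(replicate(6, base, simplify = FALSE),
                       paste0("i", 1:6))
  rr <- assess_representativeness(loc_sets, h = 1, n_iterations = 10,
                                  seed = 2)
  expect_true(rr$usable)
  expect_gt(rr$representativeness, 95)
  # inclusion near the isopleth level at every sample size
  expect_true(all(abs(rr$curve$inclusion - 0.5) < 0.15))
})

test_that("too-small samples are unusable, not an error", {
  base <- data.frame(x = rnorm(30), y = rnorm(30))
  rr <- assess_representativeness(list(a = base, b = base), h = 1)
  expect_false(rr$usable)
  expect_match(rr$reason, "fewer than 3")
})

test_that("representativeness does not decrease with sample size on
           nested synthetic datasets", {
  reps <- vapply(c(4, 8, 14), function(N) {
    set.seed(100 + N)
    loc_sets <- lapply(seq_len(N), function(i)
      data.frame(x = rnorm(60, 0, 2), y = rnorm(60, 0, 2)))
    names(loc_sets) <- paste0("i", seq_len(N))
    r <- assess_representativeness(loc_sets, h = 1, n_iterations = 15,
                                   seed = 3)
    r$representativeness
  }, numeric(1))
  expect_true(all(diff(reps) > -5))  # monotone up to bootstrap noise
})

test_that("key-area cell arithmetic follows the population threshold", {
  m <- matrix(FALSE, 8, 8)
  core <- m; core[3:5, 3:5] <- TRUE
  # unanimity at full representativeness reproduces the shared polygon
  isos <- setNames(replicate(10, mask_iso(core), simplify = FALSE),
                   paste0("i", 1:10))
  ka <- find_site(isos, 100, threshold_pct = 10)
  expect_equal(ka$mask, core)
  expect_equal(ka$area_km2, 9)
  expect_true(all(ka$surface[core] == 100))

  # 1 of 20 individuals uses an extra cell: 5% < 10% -> excluded
  odd <- core; odd[7, 7] <- TRUE
  isos20 <- c(setNames(replicate(19, mask_iso(core), simplify = FALSE),
                       paste0("i", 1:19)),
              list(i20 = mask_iso(odd)))
  ka20 <- find_site(isos20, 100, threshold_pct = 10)
  expect_false(ka20$mask[7, 7])

  # 3 of 20 with representativeness 50%: 15% x 0.5 = 7.5% < 10%
  isos3 <- c(setNames(replicate(17, mask_iso(core), simplify = FALSE),
                      paste0("i", 1:17)),
             setNames(replicate(3, mask_iso(odd), simplify = FALSE),
                      paste0("j", 1:3)))
  ka3 <- find_site(isos3, 50, threshold_pct = 10)
  expect_equal(ka3$surface[7, 7], 7.5)
  expect_false(ka3$mask[7, 7])
  # the same cell clears a lower threshold
  expect_true(find_site(isos3, 50, threshold_pct = 7)$mask[7, 7])

  expect_error(find_site(isos[1:5], 100), ">= 8")
})

test_that("key-area size is monotone non-increasing in the threshold", {
  set.seed(72)
  isos <- lapply(1:10, function(i) {
    m <- matrix(FALSE, 12, 12)
    cx <- sample(3:9, 1); cy <- sample(3:9, 1)
    m[cx + (-2:2), cy + (-2:2)] <- TRUE
    mask_iso(m)
  })
  names(isos) <- paste0("i", 1:10)
  areas <- vapply(c(5, 10, 20, 40, 80),
                  function(th) find_site(isos, 90, th)$area_km2,
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("rigid translation of all isopleths translates the key area", {
  m <- matrix(FALSE, 12, 12)
  core <- m; core[3:5, 3:5] <- TRUE
  shifted <- m; shifted[6:8, 5:7] <- TRUE
  isos_a <- setNames(replicate(8, mask_iso(core), simplify = FALSE),
                     paste0("i", 1:8))
  isos_b <- setNames(replicate(8, mask_iso(shifted), simplify = FALSE),
                     paste0("i", 1:8))
  ka_a <- find_site(isos_a, 100)
  ka_b <- find_site(isos_b, 100)
  expect_equal(ka_a$area_km2, ka_b$area_km2)
  expect_equal(which(ka_b$mask, arr.ind = TRUE)[, 1] -
                 which(ka_a$mask, arr.ind = TRUE)[, 1],
               rep(3, 9))
})

test_that("the comparison table applies the 70% representativeness rule", {
  est <- data.frame(
    colony_id = rep(c("A", "B", "C"), each = 5),
    subset = rep(c("all", "sample", "resting", "foraging", "transiting"),
                 3),
    level = 0.5,
    area_km2 = c(rep(100, 5), rep(200, 5), rep(300, 5)),
    representativeness = c(rep(95, 5), rep(65, 5), rep(80, 5)))
  tab <- suppressMessages(compare_key_area_sizes(est))
  expect_setequal(unique(tab$colony_id), c("A", "C"))
  expect_equal(nrow(tab), 10)
  expect_equal(tab$log10_area, log10(tab$area_km2), tolerance = 1e-12)
  expect_equal(unique(attr(tab, "exclusions")$colony_id), "B")
})
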