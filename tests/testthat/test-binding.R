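params <- binding_params()  # threshold 43.5 nm

test_that("particles beyond the threshold stay unbound, closest fibril wins", {
  # one particle 100 nm above the only fibril
  ann <- mk_set(matrix(c(50, 100), 1), matrix(c(0, 0, 100, 0), 1))
  a <- assign_particles(ann, params)
  expect_equal(a$status, "unbound")
  expect_true(is.na(a$fibril_id))
  expect_equal(a$distance, 100)

  # distances 20 and 30 to fibrils A and B: bound to the closer A
  ann <- mk_set(matrix(c(50, 20), 1),
                matrix(c(0, 0, 100, 0,      # f001 at distance 20
                         0, 50, 100, 50),   # f002 at distance 30
                       2, byrow = TRUE))
  a <- assign_particles(ann, params)
  expect_equal(a$status, "bound")
  expect_equal(a$fibril_id, "f001")
  expect_equal(a$distance, 20)

  # exact tie: first fibril in file order wins
  ann <- mk_set(matrix(c(50, 25), 1),
                matrix(c(0, 0, 100, 0, 0, 50, 100, 50), 2, byrow = TRUE))
  a <- assign_particles(ann, params)
  expect_equal(a$fibril_id, "f001")

  # the boundary is inclusive: a particle exactly at the threshold is bound
  ann <- mk_set(matrix(c(50, 43.5), 1), matrix(c(0, 0, 100, 0), 1))
  expect_equal(assign_particles(ann, params)$status, "bound")
})

test_that("empty particle or fibril lists are handled, not errors", {
  ann <- mk_set(matrix(numeric(0), 0, 2), matrix(c(0, 0, 100, 0), 1))
  expect_equal(nrow(assign_particles(ann, params)), 0)

  ann <- mk_set(matrix(c(1, 2), 1), matrix(numeric(0), 0, 4))
  a <- assign_particles(ann, params)
  expect_equal(a$status, "unbound")
  expect_true(is.na(a$distance))
  s <- score_fibrils(a, ann)
  expect_equal(nrow(s), 0)
})

test_that("assignments match the brute-force all-pairs oracle", {
  set.seed(515)
  for (i in 1:30) {
    ann <- random_instance(sample(1:50, 1), sample(1:8, 1), extent = 600)
    got <- assign_particles(ann, params)
    want <- oracle_assign(ann, params)
    expect_equal(got$status, want$status)
    expect_equal(got$fibril_id, want$fibril_id)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
})

test_that("bound counts are conserved and each particle counted once", {
  set.seed(616)
  ann <- random_instance(80, 6, extent = 500)
  a <- assign_particles(ann, params)
  s <- score_fibrils(a, ann)
  expect_equal(nrow(a), nrow(ann$particles))
  expect_equal(sum(s$bound_count), sum(a$status == "bound"))
  expect_equal(nrow(s), nrow(ann$fibrils))        # zero-count fibrils kept
  expect_true(all(s$score * s$length_nm - s$bound_count < 1e-12))
  # every bound particle appears in exactly one fibril's count
  expect_equal(sum(table(a$fibril_id[a$status == "bound"])),
               sum(a$status == "bound"))
})

test_that("raising the threshold never unbinds a particle", {
  set.seed(717)
  ann <- random_instance(60, 5, extent = 400)
  lo <- assign_particles(ann, binding_params(r = 2, a = 10, d = 8))
  hi <- assign_particles(ann, binding_params(r = 5, a = 30, d = 17))
  expect_true(all(which(lo$status == "bound") %in%
                  which(hi$status == "bound")))
  s_lo <- score_fibrils(lo, ann); s_hi <- score_fibrils(hi, ann)
  expect_true(all(s_hi$bound_count >= s_lo$bound_count))
})

test_that("scaling coordinates and threshold together changes nothing", {
  set.seed(818)
  ann <- random_instance(40, 4, extent = 300)
  base <- assign_particles(ann, params)
  s <- 2  # power of two: exact in floating point
  ann2 <- ann
  ann2$particles$x <- s * ann$particles$x
  ann2$particles$y <- s * ann$particles$y
  for (col in c("x1", "y1", "x2", "y2")) {
    ann2$fibrils[[col]] <- s * ann$fibrils[[col]]
  }
  ann2$fibrils$length <- s * ann$fibrils$length
  scaled <- assign_particles(ann2, binding_params(r = s * 5, a = s * 30,
                                                  d = s * 17))
  expect_equal(scaled$status, base$status)
  expect_equal(scaled$fibril_id, base$fibril_id)
  expect_equal(scaled$distance, s * base$distance)
})

test_that("per-fibril scores divide bound counts by length", {
  # 4 particles within threshold of a 200 nm fibril: score 0.02 /nm
  ann <- mk_set(matrix(c(20, 10, 60, -10, 120, 5, 180, 0), 4, byrow = TRUE),
                matrix(c(0, 0, 200, 0), 1))
  s <- score_fibrils(assign_particles(ann, params), ann)
  expect_equal(s$bound_count, 4L)
  expect_equal(s$score, 0.02)

  # unknown fibril in the assignments is a consistency error
  bad <- assign_particles(ann, params)
  bad$fibril_id[1] <- "f999"
  expect_error(score_fibrils(bad, ann), "unknown fibril_id.*f999")
})

test_that("crowding filter retains greedily in file order", {
  # two parallel fibrils 10 nm apart: the second violates separation
  fib <- tibble::tibble(fibril_id = c("f1", "f2"),
                        x1 = c(0, 0), y1 = c(0, 10),
                        x2 = c(100, 100), y2 = c(0, 10))
  kept <- crowding_filter(fib, min_separation = 43.5)
  expect_equal(kept$fibril_id, "f1")

  # pairwise separation satisfied: all retained
  far <- tibble::tibble(fibril_id = c("f1", "f2", "f3"),
                        x1 = c(0, 0, 0), y1 = c(0, 100, 200),
                        x2 = c(50, 50, 50), y2 = c(0, 100, 200))
  expect_equal(crowding_filter(far, 43.5)$fibril_id, far$fibril_id)

  # min_separation = 0 is the identity
  expect_identical(crowding_filter(fib, 0), fib)

  # crossing fibrils have distance zero: the later one is dropped
  cross <- tibble::tibble(fibril_id = c("f1", "f2"),
                          x1 = c(0, 0), y1 = c(0, 50),
                          x2 = c(100, 100), y2 = c(100, 40))
  expect_equal(crowding_filter(cross, 1)$fibril_id, "f1")
})
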