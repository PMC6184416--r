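test_that("sharing coefficient follows a_i / (a - a_p)", {
  expect_equal(sharing_coefficient(100, 1000, 0), 0.10)
  expect_equal(sharing_coefficient(0, 1000, 0), 0)
  expect_equal(sharing_coefficient(50, 1050, 50), 0.05)
  # coefficients over an institution's non-preventive records sum to 1
  a_i <- c(30, 50, 20)
  expect_equal(sum(sharing_coefficient(a_i, sum(a_i) + 10, 10)), 1)
  expect_error(sharing_coefficient(10, 100, 100),
               class = "cceann_degenerate_institution_error")
  expect_error(sharing_coefficient(-1, 100, 0),
               class = "cceann_validation_error")
})

make_inst <- function(a_i, preventive = rep(FALSE, length(a_i)),
                      ST_INC = 0, ST_ALL = 0, S_P_ALL = 0) {
  records <- tibble::tibble(
    record_id = sprintf("r%d", seq_along(a_i)),
    institution_id = "H1",
    curative_income = a_i,
    is_preventive = preventive
  )
  ledger <- tibble::tibble(institution_id = "H1", institution_type = "x",
                           ST_INC = ST_INC, ST_ALL = ST_ALL,
                           S_P_ALL = S_P_ALL)
  list(records = records, ledger = ledger)
}

test_that("income apportionment is a proportional split net of prevention", {
  f <- make_inst(c(30, 70), ST_INC = 200)
  expect_equal(allocate_income(f$records, f$ledger), c(60, 140))

  f <- make_inst(100, ST_INC = 123.4)
  expect_equal(allocate_income(f$records, f$ledger), 123.4)

  # preventive record shrinks the pool by a_p/a and gets nothing itself:
  # a = 100, a_p = 20, pool = 300 * (1 - 20/100) = 240 split 50/50
  f <- make_inst(c(40, 40, 20), preventive = c(FALSE, FALSE, TRUE),
                 ST_INC = 300)
  inc <- allocate_income(f$records, f$ledger)
  expect_equal(inc, c(120, 120, 0))
  expect_equal(sum(inc), 300 * (1 - 20 / 100))
})

test_that("allowance apportionment splits ST_ALL - S_P_ALL", {
  f <- make_inst(c(25, 75), ST_ALL = 110, S_P_ALL = 10)
  expect_equal(allocate_allowance(f$records, f$ledger), c(25, 75))

  f <- make_inst(c(25, 75), ST_ALL = 50, S_P_ALL = 50)
  expect_equal(allocate_allowance(f$records, f$ledger), c(0, 0))

  f <- make_inst(c(10, 30, 60), ST_ALL = 500, S_P_ALL = 100)
  expect_equal(allocate_allowance(f$records, f$ledger), c(40, 120, 240))

  f <- make_inst(10, ST_ALL = 100, S_P_ALL = 200)
  expect_error(allocate_allowance(f$records, f$ledger),
               class = "cceann_validation_error")
})

test_that("cce is exactly income plus allowance and respects lookups", {
  alloc <- allocate_cce(tiny_records(), tiny_ledgers())
  expect_equal(alloc$cce, alloc$allocated_income + alloc$allocated_allowance)
  expect_equal(alloc$allocated_income[tiny_records()$is_preventive], 0)
  expect_equal(alloc$record_id, tiny_records()$record_id)

  bad <- dplyr::mutate(tiny_records(), institution_id = "H9")
  expect_error(allocate_cce(bad, tiny_ledgers()),
               class = "cceann_lookup_error")
})

test_that("allocations conserve ledger totals per institution", {
  sim <- simulate_dataset(sim_config(n_records = 5000, n_institutions = 25,
                                     seed = 21))
  alloc <- allocate_cce(sim$records, sim$ledgers)
  joined <- dplyr::inner_join(
    alloc, sim$records[, c("record_id", "institution_id")], by = "record_id"
  )
  got <- dplyr::summarise(
    dplyr::group_by(joined, institution_id),
    inc = sum(allocated_income), alw = sum(allocated_allowance)
  )
  ap <- dplyr::summarise(
    dplyr::group_by(sim$records, institution_id),
    a = sum(curative_income),
    a_p = sum(curative_income[is_preventive])
  )
  m <- Reduce(function(x, y) dplyr::inner_join(x, y, by = "institution_id"),
              list(got, ap, sim$ledgers))
  expect_lt(max(abs(m$inc - m$ST_INC * (1 - m$a_p / m$a))), 1e-6)
  expect_lt(max(abs(m$alw - (m$ST_ALL - m$S_P_ALL))), 1e-6)
})

test_that("allocation is scale-equivariant and permutation-invariant", {
  rec <- tiny_records()
  led <- tiny_ledgers()
  base <- allocate_cce(rec, led)

  c_mult <- 3.7
  rec2 <- dplyr::mutate(rec, curative_income = curative_income * c_mult)
  led2 <- dplyr::mutate(led, ST_INC = ST_INC * c_mult,
                        ST_ALL = ST_ALL * c_mult, S_P_ALL = S_P_ALL * c_mult)
  expect_equal(allocate_cce(rec2, led2)$cce, base$cce * c_mult)

  perm <- c(4, 2, 6, 1, 3, 5)
  shuffled <- allocate_cce(rec[perm, ], led)
  expect_equal(
    shuffled$cce[match(base$record_id, shuffled$record_id)],
    base$cce
  )
})

test_that("institutions with no allocatable records go to the bucket", {
  rec <- tiny_records()[1:3, ] # only H1 sampled
  led <- tiny_ledgers()
  alloc <- allocate_cce(rec, led)
  bucket <- attr(alloc, "unallocated")
  expect_equal(bucket$institution_id, "H2")
  expect_equal(bucket$unallocated, 10000 + 1500 - 100)
})

test_that("dimensional totals match a brute-force per-record sum", {
  sim <- simulate_dataset(sim_config(n_records = 3000, n_institutions = 12,
                                     seed = 22))
  alloc <- allocate_cce(sim$records, sim$ledgers)
  got <- total_cce(alloc, sim$records, by = "institution_type")

  # independent oracle: plain per-record loop over types
  df <- dplyr::inner_join(alloc, sim$records, by = "record_id")
  for (ty in unique(df$institution_type)) {
    s <- 0
    for (i in seq_len(nrow(df))) {
      if (df$institution_type[i] == ty) s <- s + df$cce[i]
    }
    expect_equal(got$cce[got$group == ty], s)
  }

  # conservation: breakdown sums to the grand total
  grand <- total_cce(alloc, sim$records)$cce
  expect_equal(sum(got$cce), grand)
  expect_equal(sum(total_cce(alloc, sim$records, by = "age_band")$cce), grand)

  expect_error(total_cce(alloc, sim$records, by = "shoe_size"),
               class = "cceann_usage_error")
})

test_that("setting-stratified apportionment still conserves totals", {
  # with no preventive carve-out, both apportionment modes must hand out
  # exactly the same ledger money, just sliced differently
  sim <- simulate_dataset(sim_config(n_records = 2000, n_institutions = 10,
                                     preventive_fraction = 0, seed = 23))
  plain <- allocate_cce(sim$records, sim$ledgers)
  strat <- allocate_cce(sim$records, sim$ledgers, setting_strata = TRUE)
  expect_equal(strat$record_id, sim$records$record_id)
  expect_equal(sum(strat$cce) + sum(attr(strat, "unallocated")$unallocated),
               sum(plain$cce) + sum(attr(plain, "unallocated")$unallocated))
  expect_true(all(strat$cce >= 0))
})
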