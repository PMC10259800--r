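# Respondent schema, effects coding and WTP bound intervals.

test_that("the four response patterns map to the documented WTP intervals", {
  d <- data.frame(bid1 = c(100, 100, 200, 200), z1 = c(1, 0, 1, 0),
                  bid2 = c(150, 50, 250, 150), z2 = c(1, 0, 0, 1))
  b <- wtp_bounds(d)
  expect_equal(b$pattern, factor(c("YY", "NN", "YN", "NY"),
                                 levels = c("YY", "YN", "NY", "NN")))
  expect_equal(b$lower, c(150, 0, 200, 150))
  expect_equal(b$upper, c(Inf, 50, 250, 200))
  # configurable lower truncation
  b2 <- wtp_bounds(d, floor = -Inf)
  expect_equal(b2$lower[2], -Inf)
})

test_that("YY/YN/NY/NN intervals partition [floor, Inf) for every bid", {
  design <- bid_design()
  for (b1 in design$initial_bids) {
    up <- b1 + design$increment
    down <- b1 - design$increment
    # deterministic respondent with latent WTP w answering both questions
    w <- c(seq(0, 500, by = 12.5), down, b1, up)  # includes the breakpoints
    z1 <- as.integer(w >= b1)
    bid2 <- ifelse(z1 == 1, up, down)
    z2 <- as.integer(w >= bid2)
    bounds <- wtp_bounds(data.frame(bid1 = b1, z1 = z1,
                                    bid2 = bid2, z2 = z2))
    # each w lies in its own interval ...
    expect_true(all(w >= bounds$lower & w < bounds$upper))
    # ... and the four distinct intervals are disjoint and exhaustive
    pats <- unique(bounds[c("lower", "upper")])
    pats <- pats[order(pats$lower), ]
    expect_equal(pats$lower[1], 0)
    expect_true(all(pats$upper[-nrow(pats)] == pats$lower[-1]))
    expect_equal(pats$upper[nrow(pats)], Inf)
  }
})

test_that("effects coding follows the sum-to-zero convention", {
  d <- data.frame(edu = c("A", "B", "C"))
  X <- encode_effects(d, "edu", reference = c(edu = "C"))
  expect_identical(colnames(X), c("edu=A", "edu=B"))
  expect_equal(X[2, ], c(`edu=A` = 0, `edu=B` = 1))   # level B
  expect_equal(X[3, ], c(`edu=A` = -1, `edu=B` = -1)) # reference row
  # balanced sample -> zero column means
  db <- data.frame(edu = rep(c("A", "B", "C"), 10))
  expect_equal(colMeans(encode_effects(db, "edu")), c(`edu=A` = 0, `edu=B` = 0))
  expect_error(encode_effects(data.frame(g = rep("x", 5)), "g"),
               "single observed level")
})

test_that("effects coding matches contr.sum and level effects sum to zero", {
  set.seed(42)
  d <- data.frame(f = factor(sample(letters[1:4], 60, TRUE)))
  X <- encode_effects(d, "f")
  M <- stats::model.matrix(~f, d, contrasts.arg = list(f = "contr.sum"))
  expect_equal(matrix(as.numeric(X), nrow(X)),
               matrix(as.numeric(M[, -1]), nrow(M)))
  beta <- c(`f=a` = 0.4, `f=b` = -1.1, `f=c` = 0.25)
  expect_equal(reference_effect(beta, "f") + sum(beta), 0)
})

test_that("design_matrix assembles intercept, bid and xbar", {
  d <- generate_respondents(synthetic_config(n = 150, seed = 5))
  ds <- design_matrix(d, bid = "bid1", covariates = c("education"))
  expect_identical(colnames(ds$X)[1:2], c("(Intercept)", "bid1"))
  expect_identical(ds$bid_name, "bid1")
  expect_false("bid1" %in% names(ds$xbar))
  expect_equal(ds$xbar[["(Intercept)"]], 1)
  expect_equal(ds$xbar[["education=bachelor"]],
               mean(ds$X[, "education=bachelor"]))
})

test_that("respondent CSV round-trips through validation unchanged", {
  d <- generate_respondents(synthetic_config(n = 390, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_respondents(d, path)
  d2 <- read_respondents(path)
  expect_identical(nrow(d2), 390L)
  expect_equal(d2$bid2, d$bid2)
  expect_identical(as.character(d2$education), as.character(d$education))
})

test_that("schema violations are rejected with row numbers", {
  d <- generate_respondents(synthetic_config(n = 20, seed = 2))
  bad <- d
  bad$bid2[7] <- 50; bad$bid1[7] <- 100; bad$z1[7] <- 1  # should be 150
  expect_error(validate_respondents(bad), "follow-up rule.*7")
  bad2 <- d[, setdiff(names(d), "income_band")]
  expect_error(validate_respondents(bad2), "missing columns: income_band")
  bad3 <- d
  bad3$education <- as.character(bad3$education)
  bad3$education[3] <- "doctorate"
  expect_error(validate_respondents(bad3), "unknown education label.*3")
  bad4 <- d
  bad4$bid1[2] <- 125; bad4$bid2[2] <- 125 + ifelse(bad4$z1[2] == 1, 50, -50)
  expect_error(validate_respondents(bad4), "schedule.*2")
  # labels are matched case-insensitively after trimming
  ok <- d
  ok$gender <- toupper(paste0(" ", as.character(ok$gender), " "))
  expect_silent(validate_respondents(ok))
})

test_that("a Table-3-shaped file reproduces the published totals downstream", {
  d <- respondents_from_counts(table3_counts())
  expect_identical(nrow(d), 390L)
  tab <- tabulate_responses(d)
  tot <- tab[is.na(tab$bid), ]
  expect_equal(unlist(tot[c("YY", "YN", "NY", "NN")], use.names = FALSE),
               c(194, 42, 69, 85))
})

test_that("bid design validates its invariants", {
  expect_error(bid_design(initial_bids = c(100, 100, 200)), "increasing")
  expect_error(bid_design(increment = 150), "follow-up bid")
  expect_error(bid_design(initial_bids = -5), "positive")
  d <- bid_design()
  expect_equal(followup_bid(d, c(100, 100), c(1, 0)), c(150, 50))
})

test_that("bid design reads from YAML and JSON configs", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("initial_bids: [100, 150, 200, 250, 300, 350, 400]",
               "increment: 50", "usd_rate: 0.222"), y)
  dy <- read_bid_design(y)
  expect_equal(dy$initial_bids, seq(100, 400, 50))
  expect_equal(dy$usd_rate, 0.222)
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"initial_bids": [100, 200], "increment": 50}', j)
  expect_equal(read_bid_design(j)$initial_bids, c(100, 200))
})
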