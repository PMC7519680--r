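test_that("the .inp dialect is read with frequency expansion and group assignment", {
  path <- withr::local_tempfile(fileext = ".inp")
  writeLines(c(
    "/* resightings, two groups */",
    "",
    "1011 0 1;",
    "1000 2 0;"
  ), path)
  d <- read_inp(path, group_labels = c("3", "4"))
  expect_equal(nrow(d), 3L)
  expect_equal(sum(d$history == "1011" & d$group == "4"), 1L)
  expect_equal(sum(d$history == "1000" & d$group == "3"), 2L)
})

test_that("malformed .inp records are rejected with the line number", {
  path <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("1011 1 0;", "10x1 0 1;"), path)
  expect_error(read_inp(path, c("3", "4")), "line 2.*non-binary")

  writeLines(c("1011 1 0"), path)
  expect_error(read_inp(path, c("3", "4")), "';'")

  writeLines(c("1011 1;"), path)
  expect_error(read_inp(path, c("3", "4", "5")), "frequency columns")

  writeLines(c("1011 1 0;", "1101 0 1;", "0000 1 0;"), path)
  expect_error(read_inp(path, c("3", "4")), "all-zero")
})

test_that("a mixed fixture's per-group totals equal independent column sums", {
  path <- withr::local_tempfile(fileext = ".inp")
  lines <- c(
    "10110 1 0 2;",
    "11000 0 3 0;",
    "10001 2 0 0;",
    "01100 0 1 1;",
    "00111 1 1 0;",
    "01010 0 0 2;"
  )
  writeLines(lines, path)
  d <- read_inp(path, group_labels = c("3", "4", "5"))
  # independent recount straight off the text lines
  freqs <- do.call(rbind, lapply(strsplit(gsub(";", "", lines), "\\s+"), function(f) {
    as.integer(f[-1])
  }))
  expect_equal(unname(table(d$group)[c("3", "4", "5")]), colSums(freqs),
    ignore_attr = TRUE
  )
  expect_equal(nrow(d), sum(freqs))
})

test_that("writing and re-reading the .inp dialect round-trips the dataset", {
  set.seed(7)
  d <- random_tiny_data(K = 6, n = 25, groups = c("3", "4", "7plus"))
  path <- withr::local_tempfile(fileext = ".inp")
  write_inp(d, path)
  d2 <- read_inp(path)
  key <- function(x) sort(paste(x$history, x$group))
  expect_equal(key(d2), key(d))
})

test_that("the long-format history CSV round-trips", {
  set.seed(8)
  d <- random_tiny_data(K = 5, n = 12, groups = c("4", "6"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(d, path)
  d2 <- read_history_csv(path)
  expect_equal(d2$history[match(d$id, d2$id)], d$history)
  expect_equal(as.character(d2$group[match(d$id, d2$id)]), as.character(d$group))
})

test_that("histories are re-anchored at first breeding and grouped by age", {
  # birth at the first detection; first breeding occasion = birth + age
  d <- encounter_data(
    c("10010000", "10000010", "11000000", "01000100", "10000001"),
    group = "3",
    id = c("a", "b", "c", "d", "e")
  )
  out <- transform_to_first_breeding(
    d,
    age_at_first = c(a = 3, b = 6, c = 3, d = 4, e = 7)
  )
  expect_equal(out$history[out$id == "a"], "00010000")
  expect_equal(out$history[out$id == "b"], "00000010")
  # c was never detected at or after its first breeding occasion -> dropped
  expect_false("c" %in% out$id)
  expect_equal(out$history[out$id == "d"], "00000100")
  expect_equal(as.character(out$group[out$id == "b"]), "6")
  expect_equal(as.character(out$group[out$id == "d"]), "4")
  expect_equal(as.character(out$group[out$id == "e"]), "7plus")
})

test_that("ages below 3 are rejected and ages of 7+ pool", {
  d <- encounter_data(c("1001", "1001"), group = "3", id = c("a", "b"))
  expect_error(
    transform_to_first_breeding(d, c(a = 2, b = 3)),
    "recruitment to the breeding class starts at 3"
  )
})

test_that("group sizes after transformation match a hand binning of ages", {
  set.seed(11)
  n <- 20
  K <- 14
  ages <- sample(3:9, n, replace = TRUE)
  H <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    H[i, 1L] <- 1L # all born at occasion 1
    H[i, 1L + ages[i]] <- 1L # seen at first breeding
  }
  d <- encounter_data(H, group = "3")
  out <- transform_to_first_breeding(d, ages)
  hand <- table(factor(ifelse(ages >= 7, "7plus", ages),
    levels = c("3", "4", "5", "6", "7plus")
  ))
  expect_equal(unname(table(out$group)), unname(hand), ignore_attr = TRUE)
})

test_that("a single history traces through the m-array correctly", {
  d <- encounter_data("1101", group = "5")
  m <- build_marray(d)
  got <- dplyr::select(
    tibble::as_tibble(m), "mark_class", "release", "recapture", "n"
  )
  expect_equal(nrow(got), 3L)
  expect_equal(
    got[got$mark_class == "newly_marked", ]$release, 1L
  )
  expect_equal(
    got[got$mark_class == "newly_marked", ]$recapture, 2L
  )
  prev <- got[got$mark_class == "previously_marked", ]
  expect_equal(prev$release, c(2L, 4L))
  expect_equal(prev$recapture, c(4L, NA))
})

test_that("never-reseen datasets put everyone in never_seen_again", {
  d <- encounter_data(c("100", "100", "010"), group = c("3", "3", "4"))
  m <- build_marray(d)
  expect_true(all(is.na(m$recapture)))
  expect_true(all(m$mark_class == "newly_marked"))
  expect_equal(sum(m$n), 3L)
})

test_that("m-array cell totals equal a brute-force recount over raw histories", {
  set.seed(5)
  d <- random_tiny_data(K = 7, n = 50, groups = c("3", "5", "6"))
  m <- build_marray(d)
  H <- history_matrix(d)
  # brute force: walk every history independently
  recount <- list()
  for (i in seq_len(nrow(H))) {
    det <- which(H[i, ] == 1L)
    for (k in seq_along(det)) {
      cls <- if (k == 1L) "newly_marked" else "previously_marked"
      nxt <- if (k < length(det)) det[k + 1L] else NA_integer_
      key <- paste(d$group[i], cls, det[k], nxt, sep = "|")
      recount[[key]] <- (recount[[key]] %||% 0L) + 1L
    }
  }
  got <- setNames(
    m$n,
    paste(m$group, m$mark_class, m$release, m$recapture, sep = "|")
  )
  expect_equal(sort(names(got)), sort(names(recount)))
  expect_equal(unname(got[sort(names(got))]),
    unname(unlist(recount)[sort(names(recount))]),
    ignore_attr = TRUE
  )
})

test_that("the m-array is invariant to individual ordering and conserves releases", {
  set.seed(6)
  d <- random_tiny_data(K = 6, n = 30)
  perm <- sample(nrow(d))
  d2 <- encounter_data(history_matrix(d)[perm, ],
    group = d$group[perm], id = d$id[perm]
  )
  m1 <- build_marray(d)
  m2 <- build_marray(d2)
  expect_equal(
    tibble::as_tibble(m1)[c("group", "mark_class", "release", "recapture", "n")],
    tibble::as_tibble(m2)[c("group", "mark_class", "release", "recapture", "n")]
  )
  rel <- marray_releases(m1)
  expect_equal(sum(rel$released), sum(m1$n))
  expect_silent(validate_marray(m1))
})

test_that("all-zero and ragged histories are rejected at construction", {
  expect_error(encounter_data(c("101", "000"), group = "3"), "at least one detection")
  expect_error(encounter_data(c("101", "10"), group = "3"), "same length")
  expect_error(encounter_data(c("102"), group = "3"), "0 and 1")
  expect_error(encounter_data("101", group = "9"), "unknown age")
})
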