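# Contact maps, lysine heatmaps, difference maps, hotspots.

test_that("self contact map is symmetric with a zero diagonal", {
  m <- make_structure(synthetic_spec(seed = 2))
  cm <- contact_map(m, "A", "A")
  expect_equal(cm$distances, t(cm$distances))
  expect_equal(diag(cm$distances), rep(0, length(cm$resno_a)),
               ignore_attr = TRUE)
  expect_true(all(diag(cm$contacts)))
  expect_error(contact_map(m, "A", "Z"), "unknown chain")
})

test_that("chains placed 100 A apart share no contacts at 30 A", {
  spec <- synthetic_spec(chains = data.frame(chain_id = c("A", "B"),
                                             length = c(20L, 20L),
                                             fraction_helix = 1),
                         inter_chain_offsets = list(A = c(0, 0, 0),
                                                    B = c(100, 0, 0)),
                         seed = 1)
  m <- make_structure(spec)
  cm <- contact_map(m, "A", "B", threshold = 30)
  expect_equal(sum(cm$contacts), 0L)
  expect_gte(min(cm$distances), 90)
})

test_that("contact counts equal brute-force pair enumeration", {
  m <- make_structure(synthetic_spec(seed = 6))
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    cm <- contact_map(m, pair[1], pair[2], threshold = 30)
    expect_equal(sum(cm$contacts),
                 oracle_contact_count(m, pair[1], pair[2], 30))
  }
})

test_that("contact_map(a,b) is the transpose of contact_map(b,a)", {
  m <- make_structure(synthetic_spec(seed = 9))
  ab <- contact_map(m, "A", "B")
  ba <- contact_map(m, "B", "A")
  expect_equal(ab$distances, t(ba$distances))
  expect_equal(ab$contacts, t(ba$contacts))
})

test_that("raising the threshold never removes a contact", {
  m <- make_structure(synthetic_spec(seed = 5))
  lo <- contact_map(m, "A", "B", threshold = 20)
  hi <- contact_map(m, "A", "B", threshold = 35)
  expect_true(all(hi$contacts[lo$contacts]))
})

test_that("lysine heatmap is the lysine submatrix of the contact map", {
  m <- make_structure(synthetic_spec(seed = 12))
  cm <- contact_map(m, "A", "B")
  hm <- lysine_heatmap(m, "A", "B")
  expect_equal(hm$distances,
               cm$distances[as.character(hm$lysines_a),
                            as.character(hm$lysines_b)])
  # lysines sit every 7th residue in synthetic chains
  expect_equal(hm$lysines_a, seq(1, 90, by = 7))
})

test_that("hand-placed lysines give hand-computed heatmap distances", {
  m <- toy_structure(list(
    A = data.frame(resno = 1:2, resid = c("LYS", "ALA"),
                   x = c(0, 1), y = 0, z = 0),
    B = data.frame(resno = 1:2, resid = c("LYS", "LYS"),
                   x = c(3, 0), y = c(4, 12), z = 0)))
  hm <- lysine_heatmap(m, "A", "B")
  expect_equal(dim(hm$distances), c(1L, 2L))
  expect_equal(as.numeric(hm$distances), c(5, 12))
})

test_that("a chain without lysines yields an empty heatmap axis", {
  m <- toy_structure(list(
    A = data.frame(resno = 1:3, resid = "ALA", x = 1:3, y = 0, z = 0),
    B = data.frame(resno = 1, resid = "LYS", x = 0, y = 0, z = 0)))
  hm <- lysine_heatmap(m, "A", "B")
  expect_length(hm$lysines_a, 0L)
  expect_equal(dim(hm$distances), c(0L, 1L))
})

test_that("map differences label exclusive and shared contacts", {
  m <- make_structure(synthetic_spec(seed = 3))
  cm <- contact_map(m, "A", "B")
  same <- map_difference(cm, cm)
  expect_equal(unname(same$counts[c("only_1", "only_2")]), c(0L, 0L))
  expect_equal(unname(same$counts["shared"]), sum(cm$contacts))

  # complement on a toy 3x3: everything is exclusive
  mk_map <- function(contacts) {
    structure(list(chain_a = "A", chain_b = "B", resno_a = 1:3,
                   resno_b = 1:3, distances = ifelse(contacts, 1, 99),
                   threshold = 30, contacts = contacts),
              class = "xl_contact_map")
  }
  pattern <- matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                      TRUE, FALSE, TRUE), 3, 3)
  d <- map_difference(mk_map(pattern), mk_map(!pattern))
  expect_equal(unname(d$counts["shared"]), 0L)
  expect_equal(sum(d$counts), 9L)

  expect_error(map_difference(cm, contact_map(m, "A", "C")), "mismatch")
})

test_that("a planted lost interface shows up as exclusive contacts", {
  spec <- synthetic_spec(seed = 10)
  dimer <- make_structure(spec)
  apart <- dimer
  idx <- apart$atoms$chain == "B"
  apart$atoms$x[idx] <- apart$atoms$x[idx] + 500
  m1 <- contact_map(dimer, "A", "B")
  m2 <- contact_map(apart, "A", "B")
  d <- map_difference(m1, m2)
  expect_equal(nrow(d$only_1), sum(m1$contacts))
  expect_equal(unname(d$counts[c("only_2", "shared")]), c(0L, 0L))
})

test_that("hotspots are 4-connected components of the contact matrix", {
  contacts <- matrix(FALSE, 6, 6)
  contacts[1:2, 1:2] <- TRUE          # 4-cell blob
  contacts[5:6, 5] <- TRUE            # 2-cell blob
  contacts[4, 1] <- TRUE              # singleton
  map <- structure(list(chain_a = "A", chain_b = "B", resno_a = 1:6,
                        resno_b = 1:6,
                        distances = ifelse(contacts, 1, 99),
                        threshold = 30, contacts = contacts),
                   class = "xl_contact_map")
  hs <- contact_hotspots(map)
  expect_equal(unname(hs$sizes), c(4L, 2L, 1L))
  expect_equal(nrow(hs$cells), 7L)
})

test_that("matrix output writes and plots render on a null device", {
  m <- make_structure(synthetic_spec(seed = 1))
  cm <- contact_map(m, "A", "B")
  f <- tempfile(fileext = ".tsv")
  write_map(cm, f)
  back <- as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(cm$distances), tolerance = 1e-4)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(cm))
  expect_silent(plot(lysine_heatmap(m, "A", "B")))
})
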