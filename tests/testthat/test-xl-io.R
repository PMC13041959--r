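# PDB and crosslink-table I/O, chain maps, restraint files.

test_that("read_pdb parses chains, residues and sequences from fixtures", {
  p <- write_pdb_lines(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0),
    pdb_atom_line(3, "CA", "LYS", "A", 2, 4.8, 0, 0)))
  m <- read_pdb(p)
  expect_s3_class(m, "xl_structure")
  expect_equal(chain_ids(m), "A")
  expect_equal(unname(m$chain_sequences["A"]), "AK")
  expect_equal(nrow(m$atoms), 3L)

  trimer <- make_structure(synthetic_spec(seed = 3))
  f <- tempfile(fileext = ".pdb")
  write_pdb(trimer, f)
  back <- read_pdb(f)
  expect_length(back$chain_sequences, 3L)
  expect_equal(sort(chain_ids(back)), c("A", "B", "C"))
})

test_that("first altloc wins and duplicates after resolution are rejected", {
  p <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "LYS", "A", 1, 0, 0, 0, altloc = "A"),
    pdb_atom_line(2, "CA", "LYS", "A", 1, 0.5, 0, 0, altloc = "B"),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 3.8, 0, 0)))
  n_raw <- sum(grepl("^ATOM", readLines(p)))
  m <- read_pdb(p)
  expect_equal(n_raw, 3L)
  expect_equal(nrow(m$atoms), 2L)  # one record fewer than the raw file
  expect_equal(m$atoms$x[m$atoms$resno == 1], 0)  # the first altloc

  dup <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "LYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "LYS", "A", 1, 9, 9, 9)))
  expect_error(read_pdb(dup), "duplicate")
})

test_that("read_pdb errors on missing files and models without alpha-carbons", {
  expect_error(read_pdb(tempfile()), "not found")
  p <- write_pdb_lines(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0,
                                     element = "N"))
  expect_error(read_pdb(p), "alpha-carbon")
})

test_that("PDB round-trip preserves ids, numbering and CA coordinates", {
  m <- make_structure(synthetic_spec(seed = 11))
  f <- tempfile(fileext = ".pdb")
  write_pdb(m, f)
  back <- read_pdb(f, model_id = m$model_id)
  expect_equal(back$atoms$chain, m$atoms$chain)
  expect_equal(back$atoms$resno, m$atoms$resno)
  # PDB stores 3 decimals
  expect_equal(back$atoms$x, round(m$atoms$x, 3))
  expect_equal(back$atoms$z, round(m$atoms$z, 3))
  expect_equal(back$chain_sequences, m$chain_sequences)
})

test_that("crosslink tables parse with canonical and custom dialects", {
  csms <- toy_csms(c("P1", "P1", "P2", "P2", "P3"), c(10, 10, 5, 7, 2),
                   c("P1", "P2", "P1", "P2", "P3"), c(30, 5, 10, 20, 9))
  f <- tempfile(fileext = ".tsv")
  write_crosslink_table(csms, f)
  back <- read_crosslink_table(f)
  expect_equal(nrow(back), 5L)
  expect_equal(back$protein_a, csms$protein_a)
  expect_equal(back$position_b, as.integer(csms$position_b))
  expect_true(all(back$passes_fdr))

  # a vendor-style export with different column names
  v <- data.frame(`Protein A` = "P1", `Seq pos A` = 4,
                  `Protein B` = "P2", `Seq pos B` = 9, check.names = FALSE)
  fv <- tempfile(fileext = ".csv")
  utils::write.csv(v, fv, row.names = FALSE)
  d <- xl_dialect(protein_a = "Protein A", position_a = "Seq pos A",
                  protein_b = "Protein B", position_b = "Seq pos B",
                  csm_id = NA, replicate = NA, score = NA, passes_fdr = NA)
  vb <- read_crosslink_table(fv, d)
  expect_equal(vb$position_a, 4L)
  expect_equal(vb$replicate, "1")

  # dialect round-trip through YAML
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(protein_a = "Protein A", position_a = "Seq pos A",
                        protein_b = "Protein B", position_b = "Seq pos B"),
                   fy)
  d2 <- read_dialect(fy)
  expect_equal(read_crosslink_table(fv, d2)$position_b, 9L)
})

test_that("malformed positions and unknown dialect columns are rejected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("csm_id\treplicate\tprotein_a\tposition_a\tprotein_b\tposition_b\tscore\tpasses_fdr",
               "c1\trep1\tP1\t10\tP2\t5\t1\tTRUE",
               "c2\trep1\tP1\tten\tP2\t5\t1\tTRUE"), f)
  expect_error(read_crosslink_table(f), "row 2")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("acc1\tacc2", "P1\tP2"), f2)
  expect_error(read_crosslink_table(f2), "not found")
})

test_that("crosslink mapping is total with reason-coded unmapped markers", {
  m <- toy_structure(list(A = data.frame(resno = c(10, 30),
                                         x = c(0, 10), y = 0, z = 0)))
  cm <- chain_map("P1", "A", 0L)
  u <- dedupe_crosslinks(toy_csms(
    c("P1", "P9", "P1"), c(10, 1, 10),
    c("P1", "P1", "P1"), c(30, 10, 99)))
  mapped <- map_crosslinks(u, cm, m)
  expect_equal(sort(unique(mapped$xl_id)), 1:3)  # every XL accounted for
  ok <- mapped[mapped$mapped, ]
  expect_equal(nrow(ok), 1L)
  expect_equal(c(ok$chain_a, ok$resno_a, ok$chain_b, ok$resno_b),
               c("A", "10", "A", "30"))
  bad <- mapped[!mapped$mapped, ]
  expect_setequal(bad$reason, c("no-chain", "no-residue"))
})

test_that("homo-oligomer accessions yield all candidate chain pairs", {
  m <- toy_structure(list(
    A = data.frame(resno = c(10, 30), x = c(0, 50), y = 0, z = 0),
    B = data.frame(resno = c(10, 30), x = c(40, 15), y = 0, z = 0)))
  cm <- chain_map(c("P1", "P1"), c("A", "B"), 0L)
  u <- dedupe_crosslinks(toy_csms("P1", 10, "P1", 30))
  mapped <- map_crosslinks(u, cm, m)
  expect_equal(nrow(mapped), 4L)  # 2 chains x 2 chains
  expect_true(all(mapped$mapped))
})

test_that("non-lysine mapped residues are kept but flagged with a warning", {
  m <- toy_structure(list(A = data.frame(resno = c(1, 2), resid = c("ALA", "LYS"),
                                         x = c(0, 5), y = 0, z = 0)))
  u <- dedupe_crosslinks(toy_csms("P1", 1, "P1", 2))
  expect_warning(mapped <- map_crosslinks(u, chain_map("P1", "A"), m),
                 "non-lysine")
  expect_true(all(mapped$mapped))
  expect_false(mapped$lysine_a)
  expect_true(mapped$lysine_b)
})

test_that("restraint files follow the frozen dialect layouts", {
  rs <- restraint_set("A", 10, "B", 20, target = 18.5,
                      lower_margin = 18.5, upper_margin = 18.5)
  f <- tempfile()
  write_restraints(rs, f)
  expect_equal(readLines(f),
               paste("assign (segid A and resid 10 and name CA)",
                     "(segid B and resid 20 and name CA) 18.5 18.5 18.5"))
  rs2 <- restraint_set("A", 10, "B", 20, target = 18.5,
                       lower_margin = 18.5, upper_margin = 18.5,
                       dialect = "refinement-list")
  write_restraints(rs2, f)
  expect_equal(readLines(f), "10 A 20 B 18.5")
  expect_error(write_restraints(
    restraint_set(character(), integer(), character(), integer(),
                  target = numeric(), lower_margin = numeric(),
                  upper_margin = numeric()), f), "empty")
  expect_error(restraint_set("A", 1, "B", 2, target = 5,
                             lower_margin = 8, upper_margin = 5),
               "below zero")
})

test_that("restraint files are byte-identical under input permutation", {
  set.seed(42)
  base <- data.frame(chain_a = c("B", "A", "A"), res_a = c(4L, 9L, 2L),
                     chain_b = c("C", "B", "B"), res_b = c(7L, 1L, 5L))
  files <- lapply(1:4, function(k) {
    ord <- if (k == 1) 1:3 else sample(3)
    rs <- restraint_set(base$chain_a[ord], base$res_a[ord],
                        base$chain_b[ord], base$res_b[ord],
                        target = 18.5, lower_margin = 18.5,
                        upper_margin = 18.5)
    f <- tempfile()
    write_restraints(rs, f)
    f
  })
  sums <- vapply(files, function(f) unname(tools::md5sum(f)), character(1))
  expect_length(unique(sums), 1L)
})

test_that("restraint selectors are validated against a model when given", {
  m <- toy_structure(list(A = data.frame(resno = 1:2, x = c(0, 4), y = 0,
                                         z = 0)))
  rs <- restraint_set("A", 1, "A", 99, target = 10, lower_margin = 10,
                      upper_margin = 10)
  expect_error(write_restraints(rs, tempfile(), model = m), "resolve")
})

test_that("chain maps round-trip through YAML including homo-oligomers", {
  cm <- chain_map(c("P1", "P1", "P2"), c("A", "B", "C"), c(0L, 0L, -5L))
  f <- tempfile(fileext = ".yaml")
  write_chain_map(cm, f)
  back <- read_chain_map(f)
  back <- back[order(back$accession, back$chain), ]
  rownames(back) <- NULL
  expect_equal(as.data.frame(back), as.data.frame(cm))
  expect_error(chain_map(c("P1", "P1"), c("A", "A")), "duplicate")
})

test_that("FASTA sequences round-trip", {
  seqs <- c(P1 = "MKTKK", P2 = "AAAKAAA")
  f <- tempfile(fileext = ".fasta")
  write_fasta_sequences(seqs, f)
  expect_equal(read_fasta_sequences(f), seqs)
})
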