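test_that("a synthetic poly-ALA chain round-trips through PDB", {
  chain <- chain_structure("A", make_helix(10), strrep("A", 10), 1:10)
  path <- tempfile(fileext = ".pdb")
  write_pdb_ca(chain, path)
  back <- read_chain(path, "A")
  expect_equal(n_residues(back), 10)
  expect_equal(back$sequence, "AAAAAAAAAA")
  expect_equal(back$residue_numbers, 1:10)
  expect_equal(back$ca_coords, unname(chain$ca_coords), tolerance = 1e-3)
  # parser determinism: identical bytes -> identical structure
  expect_identical(back, read_chain(path, "A"))
  # default chain selection
  expect_identical(back, read_chain(path))
  expect_error(read_chain(path, "Z"), "not found")
  expect_error(read_chain("/no/such/file.pdb"), "not found")
})

pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, alt, resn, chain, resno, x, y, z)
}

test_that("residues without a C-alpha are skipped and logged", {
  lines <- character(0)
  k <- 0
  for (r in 1:10) {
    k <- k + 1
    lines <- c(lines, pdb_line(k, " N", " ", "ALA", "A", r, r, 0, 0))
    if (r != 5) {
      k <- k + 1
      lines <- c(lines, pdb_line(k, " CA", " ", "ALA", "A", r, r, 1, 0))
    }
  }
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  expect_message(chain <- read_chain(path, "A"), "lacking a C-alpha")
  expect_equal(n_residues(chain), 9)
  expect_equal(chain$residue_numbers, setdiff(1:10, 5))
})

test_that("the first alternate location wins and HETATM/non-standard
           residues are handled", {
  lines <- c(
    pdb_line(1, " CA", " ", "ALA", "A", 1, 1.0, 0, 0),
    pdb_line(2, " CA", "A", "GLY", "A", 2, 2.5, 0, 0),
    pdb_line(3, " CA", "B", "GLY", "A", 2, 9.9, 0, 0),
    pdb_line(4, " CA", " ", "UNK", "A", 3, 4.0, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_line(5, " CA", " ", "HOH", "A", 4, 99, 0, 0)),
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  chain <- read_chain(path, "A")
  expect_equal(n_residues(chain), 3)           # HETATM ignored
  expect_equal(chain$ca_coords[2, 1], 2.5)     # altloc A, not B
  expect_equal(substr(chain$sequence, 3, 3), "X")
})

test_that("domains are cut by author-numbered ranges", {
  chain <- chain_structure("A", make_helix(20), strrep("A", 20), 1:20)
  d <- extract_domain(chain, list(c(1, 10)), "d1")
  expect_equal(n_residues(d), 10)
  disc <- extract_domain(chain, list(c(1, 5), c(11, 15)), "d2", order = 1L)
  expect_equal(n_residues(disc), 10)
  expect_equal(disc$residue_ranges, list(c(1, 5), c(11, 15)))
  expect_equal(disc$ca_coords, chain$ca_coords[c(1:5, 11:15), ])
  expect_error(extract_domain(chain, list(c(21, 30)), "d3"), "selects no")
  expect_error(extract_domain(chain, list(c(1, 8), c(5, 12)), "d4"),
               "overlapping")
  expect_error(extract_domain(chain, list(), "d5"), "empty")
})

test_that("domain definition TSVs drive extraction", {
  dir <- tempfile(); dir.create(dir)
  chain <- chain_structure("Q", make_helix(30), strrep("A", 30), 1:30)
  write_pdb_ca(chain, file.path(dir, "Q.pdb"), chain = "Q")
  tsv <- file.path(dir, "domains.tsv")
  writeLines(c("domain_id\tchain_id\torder_in_chain\tranges",
               "Q_d1\tQ\t0\t1-12",
               "Q_d2\tQ\t1\t13-20;25-30"), tsv)
  doms <- read_domain_tsv(tsv)
  expect_length(doms, 2)
  expect_equal(n_residues(doms[[1]]), 12)
  expect_equal(n_residues(doms[[2]]), 14)
  expect_equal(doms[[2]]$order_in_chain, 1L)
})

test_that("database containers round-trip bit-exactly", {
  model <- toy_model(seed = 81, init_sd = 0.05)
  doms <- lapply(1:3, function(i) random_domain(15, sprintf("m%d", i),
                                                seed = i))
  db <- createdb(doms, model, metadata = c("a", "b", "c"))
  dir <- tempfile()
  write_db(db, dir)
  back <- read_db(dir)
  expect_identical(back$embeddings, db$embeddings)
  expect_identical(lapply(back$records, `[[`, "ca_coords"),
                   lapply(db$records, `[[`, "ca_coords"))
  expect_equal(vapply(back$records, `[[`, "", "domain_id"),
               vapply(db$records, `[[`, "", "domain_id"))
  expect_identical(back$metadata, db$metadata)
  expect_identical(back$model_fingerprint, db$model_fingerprint)
  # matching model passes silently; a different model warns
  expect_silent(read_db(dir, model = model))
  expect_warning(read_db(dir, model = toy_model(seed = 82)), "fingerprint")
})

test_that("an empty database is a valid container and searches return
           nothing", {
  model <- toy_model(seed = 83)
  db <- createdb(list(), model)
  dir <- tempfile()
  write_db(db, dir)
  back <- read_db(dir)
  expect_equal(nrow(back$embeddings), 0)
  expect_equal(nrow(topk_cosine(rnorm(model$config$embed_dim), back, 5)), 0)
})

test_that("large embedding blocks keep unit norms through the container", {
  set.seed(84)
  emb <- matrix(rnorm(1000 * 16), 1000, 16)
  db <- stub_db(emb)
  dir <- tempfile()
  write_db(db, dir)
  back <- read_db(dir)
  expect_true(all(abs(sqrt(rowSums(back$embeddings^2)) - 1) < 1e-6))
  expect_identical(back$embeddings, db$embeddings)
})
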