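# OBO parsing and controlled-vocabulary queries.

chain_obo <- function(n, shuffle_seed = NULL) {
  # linear chain T1 <- T2 <- ... <- Tn (is_a towards lower numbers)
  stanzas <- lapply(seq_len(n), function(i) {
    c("[Term]", sprintf("id: CH:%07d", i), sprintf("name: chain term %d", i),
      if (i > 1L) sprintf("is_a: CH:%07d ! parent", i - 1L), "")
  })
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    stanzas <- stanzas[sample(n)]
  }
  paste(unlist(stanzas), collapse = "\n")
}

test_that("a [Term] stanza parses into a term with its fields", {
  store <- load_obo(c("[Term]", "id: QCX:0000001", "name: toy metric count"))
  expect_length(store$terms, 1L)
  t <- cv_lookup(store, "QCX:0000001")
  expect_identical(t$name, "toy metric count")
  expect_identical(t$value_type, "unspecified")
})

test_that("is_a, obsolescence and value-type annotations are captured", {
  store <- cv_store_cached()
  tic <- cv_lookup(store, "QCX:0000004")
  expect_identical(tic$parents, "QCX:0000000")
  expect_identical(tic$value_type, "table")
  expect_setequal(tic$required_columns, c("rt", "intensity"))
  expect_true(cv_lookup(store, "QCX:0000099")$is_obsolete)
  expect_null(cv_lookup(store, "QCX:4242424"))
})

test_that("parse errors name the offending stanza or id", {
  expect_error(load_obo(c("[Term]", "name: no id here")), "line 1")
  expect_error(load_obo(c("", "[Term]", "name: x", "", "[Term]", "id: A:1")),
               "line 2")
  expect_error(
    load_obo(c("[Term]", "id: A:1", "", "[Term]", "id: A:1")),
    "duplicate OBO term id 'A:1'")
})

test_that("[Typedef] stanzas are skipped", {
  store <- load_obo(c("[Typedef]", "id: part_of", "", "[Term]", "id: A:1",
                      "name: a"))
  expect_length(store$terms, 1L)
})

test_that("descendant queries are reflexive and follow is_a", {
  store <- cv_store_cached()
  expect_true(cv_is_descendant(store, "QCX:0000004", "QCX:0000000"))
  expect_true(cv_is_descendant(store, "QCX:0000004", "QCX:0000004"))
  expect_false(cv_is_descendant(store, "QCX:0000000", "QCX:0000004"))
  expect_error(cv_is_descendant(store, "QCX:0000004", "NOPE:1"),
               "does not resolve")
})

test_that("reachability matches a breadth-first-search oracle on a chain", {
  store <- load_obo(chain_obo(10))
  accs <- sprintf("CH:%07d", 1:10)
  # oracle: explicit frontier expansion over the raw parent lists
  bfs_reachable <- function(from, to) {
    frontier <- from
    seen <- character()
    while (length(frontier)) {
      if (to %in% frontier) return(TRUE)
      seen <- union(seen, frontier)
      frontier <- setdiff(
        unlist(lapply(frontier, function(a) store$terms[[a]]$parents)), seen)
    }
    FALSE
  }
  for (a in accs) {
    for (b in accs) {
      expect_identical(cv_is_descendant(store, a, b), bfs_reachable(a, b),
                       label = sprintf("%s -> %s", a, b))
    }
  }
})

test_that("stanza order does not change lookups or reachability", {
  s1 <- load_obo(chain_obo(10))
  s2 <- load_obo(chain_obo(10, shuffle_seed = 9))
  expect_setequal(names(s1$terms), names(s2$terms))
  expect_identical(cv_is_descendant(s1, "CH:0000010", "CH:0000001"),
                   cv_is_descendant(s2, "CH:0000010", "CH:0000001"))
})

test_that("an is_a cycle is an error, not an infinite loop", {
  cyc <- c("[Term]", "id: A:1", "is_a: A:2", "", "[Term]", "id: A:2",
           "is_a: A:1")
  expect_error(load_obo(cyc), "cycle")
})

test_that("dangling parents are recorded, and files load via read_obo", {
  store <- load_obo(c("[Term]", "id: A:1", "is_a: B:9"))
  expect_identical(store$dangling, "B:9")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(toy_cv_obo(), path)
  expect_identical(names(read_obo(path)$terms), names(cv_store_cached()$terms))
  expect_error(read_obo(file.path(tempdir(), "missing.obo")),
               class = "mzqc_io_error")
})
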