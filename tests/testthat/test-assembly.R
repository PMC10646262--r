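test_that("splints are 30-nt bridges that hybridize their own junction only", {
  set.seed(21)
  a <- fragment("A", random_seq(100))
  b <- fragment("B", random_seq(100))
  c <- fragment("C", random_seq(100))
  sp <- design_splint(a, b)
  expect_identical(nchar(sp$seq), 30L)
  expect_identical(sp$seq, revcomp(paste0(substr(a$seq, 86, 100), substr(b$seq, 1, 15))))
  expect_true(ligate(a, b, sp)$ligated > 0)
  expect_false(design_splint(a, b)$seq == design_splint(a, c)$seq)
  expect_error(design_splint(fragment("s", "ACGTACGTAC"), b), "at least 15")
})

test_that("mismatched splints and unphosphorylated acceptors give no product", {
  set.seed(22)
  a <- fragment("A", random_seq(100)); b <- fragment("B", random_seq(100))
  c <- fragment("C", random_seq(100))
  wrong <- design_splint(a, c)
  res <- ligate(a, b, wrong)
  expect_null(res$product)
  expect_identical(res$ligated, 0)
  # no-ligation control: downstream 5' end not phosphorylated
  b_nop <- fragment("B", b$seq, phosphorylated = FALSE)
  expect_null(ligate(a, b_nop, design_splint(a, b_nop))$product)
})

test_that("product length is the exact sum of inputs and copies are conserved", {
  set.seed(23)
  a <- fragment("A", random_seq(90), copies = 1000)
  b <- fragment("B", random_seq(110), copies = 600)
  res <- ligate(a, b, design_splint(a, b), yield_model(0.185))
  expect_identical(nchar(res$product$seq), 200L)
  expect_equal(res$product$copies, 600 * 0.185)
  # conservation at the junction, exact arithmetic
  expect_equal(res$product$copies + res$leftovers[[1]]$copies, 1000)
  expect_equal(res$product$copies + res$leftovers[[2]]$copies, 600)
})

test_that("three 90-nt fragments ligated at two junctions give a 270-nt product", {
  set.seed(24)
  frags <- lapply(1:3, function(i) fragment(paste0("f", i), random_seq(90),
                                            copies = 1000))
  out <- serial_pool(frags)
  ladder <- size_ladder(out)
  expect_true(270L %in% ladder$length)
  top <- out$members[[which.max(vapply(out$members, function(f) nchar(f$seq),
                                       integer(1)))]]
  expect_identical(nchar(top$seq), 270L)
  expect_identical(top$seq, paste0(frags[[1]]$seq, frags[[2]]$seq, frags[[3]]$seq))
})

test_that("serial efficiency compounds multiplicatively (e^n)", {
  set.seed(25)
  frags <- lapply(1:5, function(i) fragment(paste0("f", i), random_seq(100),
                                            copies = 1e6))
  out <- serial_pool(frags, yield_model(0.185))
  top <- Filter(function(f) nchar(f$seq) == 500L, out$members)
  expect_length(top, 1L)
  expect_equal(top[[1]]$copies, 1e6 * 0.185^4)
  # the four-junction yield is at the 0.1% order of magnitude
  expect_equal(serial_efficiency(0.185, 4), 0.1)
})

test_that("programmed splint order permutes the assembled sequence", {
  set.seed(26)
  frags <- lapply(1:5, function(i) fragment(LETTERS[i], random_seq(100),
                                            copies = 1e6))
  abcde <- serial_pool(frags)
  adcbe <- serial_pool(frags[c(1, 4, 3, 2, 5)])
  p1 <- Filter(function(f) nchar(f$seq) == 500L, abcde$members)[[1]]
  p2 <- Filter(function(f) nchar(f$seq) == 500L, adcbe$members)[[1]]
  expect_identical(nchar(p1$seq), nchar(p2$seq))
  expect_false(p1$seq == p2$seq)
  expect_identical(p1$seq, paste0(vapply(frags, `[[`, character(1), "seq"),
                                  collapse = ""))
  expect_identical(p2$seq, paste(vapply(frags[c(1, 4, 3, 2, 5)], `[[`,
                                        character(1), "seq"), collapse = ""))
})

test_that("a parallel step with three splints yields three product species", {
  set.seed(27)
  up <- fragment("head", random_seq(120), copies = 3e3)
  tails <- lapply(c("Apple", "Orange", "Grape"), function(w)
    fragment(w, random_seq(70), copies = 1e3))
  splints <- lapply(tails, function(t) design_splint(up, t))
  step <- parallel_step("dU", "dT", "out", splints)
  pools <- run_program(assembly_program(list(step)),
                       list(dU = pool(up), dT = pool(tails)))
  products <- Filter(function(f) nchar(f$seq) == 190L, pools$out$members)
  expect_length(products, 3L)
  expect_setequal(vapply(products, `[[`, character(1), "id"),
                  c("head+Apple", "head+Orange", "head+Grape"))
})

test_that("an empty program is the identity on its input pools", {
  set.seed(28)
  pools <- list(d1 = pool(fragment("A", random_seq(50), copies = 10)))
  out <- run_program(assembly_program(list()), pools)
  expect_identical(out$d1$members, pools$d1$members)
  expect_error(
    run_program(assembly_program(serial_step("d1", "nope", "x", list())), pools),
    "unknown droplet")
})

test_that("the size ladder is sorted, aggregated, and order-invariant", {
  set.seed(29)
  frs <- lapply(c(300, 100, 500, 200, 400), function(n)
    fragment(paste0("f", n), random_seq(n), copies = n))
  lad <- size_ladder(pool(frs))
  expect_identical(lad$length, c(100L, 200L, 300L, 400L, 500L))
  expect_identical(lad, size_ladder(pool(rev(frs))))
  expect_identical(nrow(size_ladder(pool(list()))), 0L)
  # two species of one length collapse to one band
  two <- pool(fragment("x", random_seq(100), copies = 2),
              fragment("y", random_seq(100), copies = 3))
  lad2 <- size_ladder(two)
  expect_identical(lad2$species, 2L)
  expect_equal(lad2$copies, 5)
})

test_that("pool FASTA + copy-number sidecar round trips", {
  set.seed(30)
  pl <- pool(fragment("A", random_seq(60), copies = 12.5),
             fragment("B", random_seq(80), copies = 3))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pool(pl, fa, tsv)
  back <- read_pool(fa, tsv)
  expect_identical(vapply(back$members, `[[`, character(1), "seq"),
                   vapply(pl$members, `[[`, character(1), "seq"))
  expect_equal(vapply(back$members, `[[`, numeric(1), "copies"), c(12.5, 3))
})
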