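test_that("scanTargets matches a brute-force walk, case-insensitively", {
  root <- makeTree(list("a/x.jpg" = 5, "a/b/y.JPG" = 7, "a/b/z.ab1" = 9))
  got <- scanTargets(root, "JPG", recursive = TRUE)
  expect_identical(got$path, oracleScan(root, "JPG"))
  expect_identical(got$name, c("y.JPG", "x.jpg"))  # lexicographic by path
  expect_identical(got$size, c(7, 5))
})

test_that("scanTargets records on-disk sizes and handles empty input", {
  root <- makeTree(list("x.fas" = 11, "sub/y.fas" = 3))
  got <- scanTargets(root, "FAS", recursive = TRUE)
  expect_identical(got$size, unname(file.size(got$path)))

  empty <- scratchDir()
  for (ty in c("JPG", "AB1", "FAS"))
    expect_identical(nrow(scanTargets(empty, ty)), 0L)

  expect_error(scanTargets(file.path(empty, "nope"), "JPG"),
               "does not exist")
})

test_that("non-recursive scans ignore subdirectories", {
  root <- makeTree(list("x.fas" = 4, "sub/y.fas" = 4))
  got <- scanTargets(root, "FAS", recursive = FALSE)
  expect_identical(got$name, "x.fas")
  expect_identical(got$path, oracleScan(root, "FAS", recursive = FALSE))
})

test_that("scans agree with the oracle on fuzzed random trees", {
  for (seed in 1:25) {
    root <- scratchDir()
    generateTree(file.path(root, "t"), depth = seed %% 3,
                 filesPerDir = c(0L, 4L),
                 duplicateNameRate = ifelse(seed %% 2 == 0, 0.3, 0),
                 seed = seed)
    for (ty in c("JPG", "AB1", "FAS")) {
      expect_identical(scanTargets(file.path(root, "t"), ty)$path,
                       oracleScan(file.path(root, "t"), ty))
      expect_identical(
        scanTargets(file.path(root, "t"), ty, recursive = FALSE)$path,
        oracleScan(file.path(root, "t"), ty, recursive = FALSE))
    }
  }
})

test_that("directory symlinks are not followed", {
  skip_on_os("windows")
  root <- makeTree(list("a/x.jpg" = 5))
  ok <- file.symlink(file.path(root, "a"), file.path(root, "loop"))
  skip_if_not(isTRUE(ok), "symlinks unavailable")
  got <- scanTargets(root, "JPG", recursive = TRUE)
  expect_identical(got$name, "x.jpg")
})

test_that("writeFileList writes one tab-separated record per entry", {
  root <- makeTree(list("a/x.jpg" = 5, "b/y.jpg" = 6, "c/z.jpg" = 7))
  entries <- scanTargets(root, "JPG")
  dest <- scratchDir()
  out <- writeFileList(entries, dest, "JPG", refDate)
  expect_identical(basename(out), "20200423_target_file_list_JPG.txt")
  lines <- readLines(out)
  expect_length(lines, 3L)
  expect_identical(lines, paste(entries$path, entries$name, sep = "\t"))

  out2 <- writeFileList(entries[0, ], scratchDir(), "AB1", refDate)
  expect_identical(readLines(out2), character())
})

test_that("recursiveCopy flattens matches byte-identically", {
  root <- makeTree(list("a/s1.ab1" = 64, "a/deep/nested/s2.ab1" = 128,
                        "a/skip.jpg" = 16))
  before <- treeChecksums(root)
  out <- recursiveCopy(root, "AB1", refDate)
  expect_identical(basename(out), "20200423_recursive_copy_AB1")
  copied <- sort(list.files(out), method = "radix")
  expect_identical(copied, c("s1.ab1", "s2.ab1"))
  expect_identical(sort(unname(tools::md5sum(list.files(out,
                                                        full.names = TRUE)))),
                   sort(unname(tools::md5sum(oracleScan(root, "AB1",
                     exclude = out)))))
  ## sources untouched
  after <- treeChecksums(root)
  expect_true(all(before %in% after))
})

test_that("recursiveCopy renames duplicate base names instead of losing them", {
  root <- makeTree(list("x/s.jpg" = 10, "y/s.jpg" = 20))
  expect_warning(out <- recursiveCopy(root, "JPG", refDate),
                 "duplicate base name")
  files <- sort(list.files(out), method = "radix")
  expect_length(files, 2L)
  expect_true("s.jpg" %in% files)
  expect_true("s_1.jpg" %in% files)
  sizes <- sort(unname(file.size(file.path(out, files))))
  expect_identical(sizes, c(10, 20))
})

test_that("recursiveCopy with no matches creates an empty folder", {
  root <- makeTree(list("a/x.txt" = 5))
  out <- recursiveCopy(root, "FAS", refDate)
  expect_true(dir.exists(out))
  expect_identical(list.files(out), character())
  expect_error(recursiveCopy(root, "FAS", refDate), "already exists")
})

test_that("planPacks is first-fit in input order", {
  e <- data.frame(path = paste0("/p/", letters[1:3]),
                  name = letters[1:3], size = c(40, 40, 40))
  plan <- planPacks(e, 100)
  expect_s4_class(plan, "PackPlan")
  expect_length(packs(plan), 2L)
  expect_identical(packs(plan)[[1]]$name, c("a", "b"))
  expect_identical(packs(plan)[[2]]$name, "c")

  single <- planPacks(e[1, ], 100)
  expect_length(packs(single), 1L)
  expect_identical(packs(single)[[1]]$name, "a")

  e$size <- c(40, 150, 40)
  expect_error(planPacks(e, 100), "'b' \\(150 bytes\\) exceeds")
  expect_error(planPacks(e, 0), "positive")
})

test_that("packing partitions any size list under the cap", {
  set.seed(424242)
  for (rep in 1:10) {
    n <- sample(50:200, 1)
    cap <- sample(500:2000, 1)
    sizes <- sample(seq_len(cap), n, replace = TRUE)
    e <- data.frame(path = sprintf("/f/%03d", seq_len(n)),
                    name = sprintf("%03d", seq_len(n)), size = sizes)
    plan <- planPacks(e, cap)
    sums <- vapply(packs(plan), function(p) sum(p$size), 0)
    expect_true(all(sums <= cap))
    flat <- do.call(rbind, packs(plan))
    expect_identical(flat$name, e$name)      # order + exhaustiveness
    expect_identical(flat$size, e$size)
    expect_false(anyDuplicated(flat$path) > 0)  # disjointness
  }
})

test_that("executePacks creates indexed folders with capped byte sums", {
  root <- makeTree(list("a.jpg" = 60, "b.jpg" = 60, "c.jpg" = 60))
  entries <- scanTargets(root, "JPG", recursive = FALSE)
  plan <- planPacks(entries, 100)
  target <- scratchDir()
  dirs <- executePacks(plan, target, "JPG", refDate)
  expect_identical(basename(dirs),
                   c("20200423_max_packs_JPG_1", "20200423_max_packs_JPG_2",
                     "20200423_max_packs_JPG_3"))
  for (d in dirs)
    expect_true(sum(file.size(list.files(d, full.names = TRUE))) <= 100)
  expect_error(executePacks(plan, target, "JPG", refDate), "already exists")

  emptyPlan <- planPacks(entries[0, ], 100)
  expect_identical(executePacks(emptyPlan, scratchDir(), "JPG", refDate),
                   character())
})

test_that("parseFileList tolerates line-ending and trailing-blank variants", {
  f1 <- tempfile(); writeChar("s1.jpg\ns2.jpg\n\n", f1, eos = NULL)
  expect_identical(parseFileList(f1), c("s1.jpg", "s2.jpg"))
  f2 <- tempfile(); writeChar("s1.jpg", f2, eos = NULL)
  expect_identical(parseFileList(f2), "s1.jpg")
  f3 <- tempfile(); writeChar("s1.jpg\r\ns2.jpg\r\n\r\n", f3, eos = NULL)
  expect_identical(parseFileList(f3), c("s1.jpg", "s2.jpg"))
  f4 <- tempfile(); writeChar("\n\n\n", f4, eos = NULL)
  expect_error(parseFileList(f4), "no file names")
  expect_error(parseFileList(tempfile()), "does not exist")
})

test_that("copyByList copies the intersection and reports the remainder", {
  root <- makeTree(list("s1.jpg" = 5, "s2.jpg" = 6, "s3.jpg" = 7))
  res <- copyByList(root, c("s1.jpg", "s3.jpg"), refDate)
  expect_identical(basename(res$folder), "20200423_copy_by_list")
  expect_identical(sort(list.files(res$folder)), c("s1.jpg", "s3.jpg"))
  expect_identical(res$missing, character())

  root2 <- makeTree(list("s1.jpg" = 5))
  res2 <- copyByList(root2, "absent.jpg", refDate)
  expect_identical(list.files(res2$folder), character())
  expect_identical(res2$missing, "absent.jpg")
})

test_that("copyByList never reaches into subdirectories", {
  root <- makeTree(list("s1.jpg" = 5, "sub/s2.jpg" = 6))
  res <- copyByList(root, "s2.jpg", refDate)
  expect_identical(list.files(res$folder), character())
  expect_identical(res$missing, "s2.jpg")
})

test_that("duplicate listed names are copied once, with a warning", {
  root <- makeTree(list("s1.jpg" = 5))
  expect_warning(res <- copyByList(root, c("s1.jpg", "s1.jpg"), refDate),
                 "duplicate")
  expect_identical(list.files(res$folder), "s1.jpg")
})
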