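# Shared fixtures: small rasters built in code, random raster generator for
# property tests, and partition comparison that ignores patch numbering.

mk_raster <- function(mat, pixel_size = 0.01, origin = NULL, year = 2001L) {
  if (is.null(origin)) origin <- c(0, nrow(mat) * pixel_size)
  burn_raster(mat, origin = origin, pixel_size = pixel_size, year = year)
}

# raster with iid random burn dates on a random subset of pixels: the
# hardest case for the temporal rule (no spatial date structure)
random_burn_raster <- function(nr = 30, nc = 30, p_burn = 0.35,
                               date_range = c(1L, 40L), seed = 1L) {
  set.seed(seed)
  m <- matrix(0L, nr, nc)
  burn <- runif(nr * nc) < p_burn
  m[burn] <- sample(seq(date_range[1], date_range[2]), sum(burn),
                    replace = TRUE)
  mk_raster(m)
}

# canonical form of a pixel partition: sorted list of sorted pixel keys
partition_of <- function(px) {
  keys <- split(paste(px$row, px$col, sep = ","), px$patch)
  unname(lapply(keys, sort))[order(vapply(lapply(keys, sort), `[`, "", 1))]
}

expect_same_partition <- function(a, b) {
  expect_equal(partition_of(a), partition_of(b))
}

# TRUE iff partition `fine` refines `coarse`: every fine patch is contained
# in exactly one coarse patch
refines <- function(fine, coarse) {
  key <- function(px) paste(px$row, px$col, sep = ",")
  coarse_of <- setNames(coarse$patch, key(coarse))
  all(vapply(split(coarse_of[key(fine)], fine$patch),
             function(v) length(unique(v)) == 1, TRUE))
}
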