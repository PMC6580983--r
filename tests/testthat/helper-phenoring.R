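# shared fixtures and independent oracles, all built in code

# independent calendar oracle: month from doy by cumulative month lengths,
# no Date arithmetic (the implementation uses as.Date)
oracle_month_from_doy <- function(year, doy) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  lengths <- c(31, if (leap) 29 else 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  ends <- cumsum(lengths)
  which(doy <= ends)[1]
}

# brute-force weekly blocking oracle: walk the doys of a year in order,
# cutting a new block after every 7 days
oracle_weekly_blocks <- function(n_days) {
  blocks <- integer(n_days)
  b <- 1L; count <- 0L
  for (d in seq_len(n_days)) {
    count <- count + 1L
    blocks[d] <- b
    if (count == 7L && b < 53L) { b <- b + 1L; count <- 0L }
  }
  blocks
}

# brute-force point-in-polygon count via an independent implementation
# (mgcv::in.out) over every pixel center
oracle_mask_count <- function(vertices, width, height) {
  centers <- cbind(rep(seq_len(width) - 1, each = height),
                   rep(seq_len(height) - 1, times = width))
  bnd <- rbind(vertices, vertices[1, ])
  sum(mgcv::in.out(bnd, centers))
}

# a small valid daily table with optional missing cells
make_test_table <- function(years = 2013, vars = c("gcc_a", "gcc_b"),
                            missing_frac = 0, seed = 42) {
  phenoring:::with_seed(seed, {
    grid <- do.call(rbind, lapply(years, function(y) {
      data.frame(year = y, doy = seq_len(phenoring::days_in_year(y)))
    }))
    for (v in vars) {
      x <- runif(nrow(grid), 0.3, 0.45)
      if (missing_frac > 0) {
        x[runif(nrow(grid)) < missing_frac] <- NA_real_
      }
      grid[[v]] <- x
    }
    pheno_table(grid, variables = vars)
  })
}

# random valid table of arbitrary shape for round-trip properties
random_pheno_table <- function(seed) {
  phenoring:::with_seed(seed, {
    years <- sample(1990:2030, sample(1:3, 1))
    n_vars <- sample(1:4, 1)
    vars <- paste0("v", seq_len(n_vars), "_", sample(letters, n_vars))
    rows <- do.call(rbind, lapply(unique(years), function(y) {
      nd <- phenoring::days_in_year(y)
      doys <- sort(sample(seq_len(nd), sample(5:40, 1)))
      data.frame(year = y, doy = doys)
    }))
    for (v in vars) {
      x <- runif(nrow(rows), 0, 1)
      x[runif(nrow(rows)) < 0.15] <- NA_real_
      rows[[v]] <- x
    }
    pheno_table(rows, variables = vars)
  })
}

expect_tables_equal <- function(a, b) {
  expect_equal(pheno_vars(a), pheno_vars(b))
  expect_equal(as.data.frame(a), as.data.frame(b))
}

demo_header_csv <- function(path) {
  writeLines(c("year,doy,gcc_aspido,gcc_cary,gcc_mic,gcc_pout",
               "2013,1,0.31,0.34,0.33,0.35",
               "2013,2,0.32,0.35,0.34,0.36"), path)
  path
}
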