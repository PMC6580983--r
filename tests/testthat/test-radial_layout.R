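demo_table <- function(years = 2012:2015, seed = 1) {
  gen_gcc_table(years, phenoring:::demo_species_params(seed))
}

test_that("bins map to clockwise-from-top angular wedges", {
  expect_equal(angle_for_bin(0, 12), c(theta_start = 0, theta_end = pi / 6))
  expect_equal(unname(angle_for_bin(11, 12)[2]), 2 * pi)
  expect_equal(unname(angle_for_bin(182, 365)[1]), 2 * pi * 182 / 365)
  expect_error(angle_for_bin(12, 12), class = "phenoring_index")
  expect_error(angle_for_bin(-1, 12), class = "phenoring_index")
})

test_that("min-max normalization hits its declared degenerate rules", {
  expect_equal(normalize_values(c(0.30, 0.35, 0.40)), c(0, 0.5, 1))
  expect_equal(normalize_values(c(2, 7)), c(0, 1))
  expect_equal(normalize_values(c(0.4, 0.4, NA)), c(0.5, 0.5, NA))
  expect_equal(normalize_values(c(NA_real_, NA_real_)), c(NA_real_, NA_real_))
})

test_that("a monthly single-year ring has exactly 12 segments", {
  tab <- demo_table(2013)
  cfg <- layout_config(ring_mode = "variables", timescale = "monthly",
                       displayed_year = 2013, variables = "gcc_mic")
  scene <- build_scene(tab, cfg)
  expect_equal(nrow(scene$rings), 1)
  expect_equal(nrow(scene$cells), 12)
})

test_that("ring modes: one ring per variable, or one per year (all-years view)", {
  tab <- demo_table()
  multi <- build_scene(tab, layout_config(ring_mode = "variables",
                                          timescale = "monthly",
                                          displayed_year = 2013))
  expect_equal(multi$rings$label, pheno_vars(tab))
  expect_equal(nrow(multi$cells), 4 * 12)
  # innermost ring = first variable
  expect_equal(multi$rings$variable[which.min(multi$rings$r_inner)], "gcc_aspido")

  all_years <- build_scene(tab, layout_config(ring_mode = "years",
                                              timescale = "monthly",
                                              variables = "gcc_mic"))
  expect_equal(all_years$rings$year, 2012:2015)
  expect_equal(nrow(all_years$cells), 4 * 12)
  expect_equal(all_years$rings$year[which.min(all_years$rings$r_inner)], 2012)

  expect_error(build_scene(tab, layout_config(ring_mode = "years",
                                              timescale = "monthly")),
               class = "phenoring_config")
  expect_error(build_scene(tab, layout_config(displayed_year = 1999,
                                              variables = "gcc_mic")),
               class = "phenoring_config")
})

test_that("cells tile the full circle without gaps or overlap", {
  tab <- demo_table(2011:2012) # includes a leap year
  for (ts in c("daily", "weekly", "monthly")) {
    scene <- build_scene(tab, layout_config(ring_mode = "years", timescale = ts,
                                            variables = "gcc_cary"))
    for (i in seq_len(nrow(scene$rings))) {
      cells <- scene$cells[scene$cells$ring_index == i - 1, ]
      expect_equal(nrow(cells), bins_in_year(scene$rings$year[i], ts))
      expect_lt(abs(sum(cells$theta_end - cells$theta_start) - 2 * pi), 1e-9)
      ord <- order(cells$theta_start)
      expect_true(all(abs(cells$theta_end[ord][-nrow(cells)] -
                            cells$theta_start[ord][-1]) < 1e-12))
    }
  }
})

test_that("scene construction is pure and missing data renders missing_color", {
  tab <- demo_table(2013)
  cfg <- layout_config(timescale = "weekly", displayed_year = 2013)
  s1 <- build_scene(tab, cfg)
  s2 <- build_scene(tab, cfg)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$rings, s2$rings)

  # an all-missing variable yields a fully missing-colored ring, legend kept
  df <- as.data.frame(tab)
  df$gcc_void <- NA_real_
  tab2 <- pheno_table(df)
  scene <- build_scene(tab2, layout_config(timescale = "monthly",
                                           displayed_year = 2013))
  void_cells <- scene$cells[scene$cells$ring_index ==
                              match("gcc_void", scene$rings$variable) - 1, ]
  expect_true(all(void_cells$fill == "grey85"))
  expect_true("gcc_void" %in% vapply(scene$legend, `[[`, "", "variable"))
})

test_that("a cell's color depends only on its own variable's values", {
  tab <- demo_table(2013)
  cfg <- layout_config(timescale = "monthly", displayed_year = 2013)
  base <- build_scene(tab, cfg)
  # permute the other variables' columns; gcc_mic's ring must not change
  df <- as.data.frame(tab)
  df$gcc_aspido <- rev(df$gcc_aspido)
  df$gcc_pout <- rev(df$gcc_pout)
  perm <- build_scene(pheno_table(df), cfg)
  pick <- function(s) {
    i <- match("gcc_mic", s$rings$variable) - 1
    s$cells$fill[s$cells$ring_index == i]
  }
  expect_identical(pick(base), pick(perm))
})

test_that("year navigation saturates at the range ends", {
  tab <- demo_table()
  cfg <- layout_config(displayed_year = 2013)
  expect_equal(next_year(cfg, tab)$displayed_year, 2014L)
  expect_equal(previous_year(next_year(cfg, tab), tab)$displayed_year, 2013L)

  at_end <- layout_config(displayed_year = 2015)
  expect_equal(next_year(at_end, tab)$displayed_year, 2015L)
  at_start <- layout_config(displayed_year = 2012)
  expect_equal(previous_year(at_start, tab)$displayed_year, 2012L)
})

test_that("comparison scenes keep ground rings at native resolution", {
  cam <- demo_table(2013)
  obs <- gen_ground_obs(2013, "monthly", seasonal_params(noise_sd = 0))
  tab <- merge_tables(list(cam, obs))
  cfg <- layout_config(timescale = "daily", displayed_year = 2013,
                       variables = c("gcc_mic", "ground_activity"))
  scene <- build_comparison_scene(tab, cfg, ground_vars = "ground_activity")
  counts <- table(scene$cells$ring_index)
  expect_equal(as.integer(counts), c(365L, 12L))
  expect_equal(scene$rings$ground, c(FALSE, TRUE))

  # empty ground set reduces exactly to build_scene
  cfg2 <- layout_config(timescale = "monthly", displayed_year = 2013,
                        variables = "gcc_mic")
  plain <- build_scene(tab, cfg2)
  red <- build_comparison_scene(tab, cfg2, ground_vars = character())
  expect_identical(plain$cells, red$cells)

  # ground-only table works standalone
  gscene <- build_comparison_scene(obs, layout_config(timescale = "monthly",
                                                      displayed_year = 2013))
  expect_equal(nrow(gscene$cells), 12)
  expect_true(all(gscene$rings$ground))

  expect_error(build_comparison_scene(tab, cfg, ground_vars = "nope"),
               class = "phenoring_lookup")
})

test_that("rendering writes valid PDF and exactly-sized, reproducible PNG", {
  scene <- build_scene(demo_table(2013),
                       layout_config(timescale = "monthly", displayed_year = 2013))
  dir <- withr::local_tempdir()

  pdf_path <- render_scene(scene, file.path(dir, "fig.pdf"))
  expect_gt(file.size(pdf_path), 1000)
  expect_equal(readBin(pdf_path, "raw", 4), charToRaw("%PDF"))

  png_path <- render_scene(scene, file.path(dir, "fig.png"), size = 300)
  arr <- png::readPNG(png_path)
  expect_equal(dim(arr)[1:2], c(300L, 300L))

  png2 <- render_scene(scene, file.path(dir, "fig2.png"), size = 300)
  expect_identical(readBin(png_path, "raw", file.size(png_path)),
                   readBin(png2, "raw", file.size(png2)))

  expect_error(render_scene(scene, file.path(dir, "fig.gif"), format = "gif"),
               class = "phenoring_parameter")
  expect_error(render_scene(scene, file.path(dir, "no/such/dir/f.pdf")),
               class = "phenoring_io")
})

test_that("default filenames come from the species/ROI labels and year span", {
  tab <- demo_table()
  s1 <- build_scene(tab, layout_config(ring_mode = "years", timescale = "monthly",
                                       variables = "gcc_mic",
                                       species = "Miconia rubiginosa", roi = "mic"))
  expect_equal(default_scene_filename(s1, "pdf"),
               "Miconia-rubiginosa_mic_2012-2015.pdf")
  s2 <- build_scene(tab, layout_config(displayed_year = 2014, species = "Cerrado",
                                       roi = "all"))
  expect_equal(default_scene_filename(s2, "png"), "Cerrado_all_2014.png")
})

test_that("scene JSON serialization is deterministic and complete", {
  scene <- build_scene(demo_table(2013),
                       layout_config(timescale = "monthly", displayed_year = 2013))
  j1 <- scene_to_json(scene)
  j2 <- scene_to_json(scene)
  expect_identical(j1, j2)
  parsed <- jsonlite::fromJSON(j1)
  expect_named(parsed, c("rings", "cells", "month_labels", "legend", "caption"))
  expect_length(parsed$cells$theta_start, nrow(scene$cells))
})
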