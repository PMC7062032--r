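test_that("fruit-colour classification follows the diet and colour rules", {
  expect_equal(classify_fruit_colour("red"), "conspicuous")
  expect_equal(classify_fruit_colour("blue"), "excluded")
  expect_equal(classify_fruit_colour("brown"), "non_conspicuous")
  expect_equal(classify_fruit_colour(c("green", "red")), "conspicuous")
  # pink alone is a conspicuous colour but not a primate-diet colour
  expect_equal(classify_fruit_colour("pink"), "excluded")
  expect_equal(classify_fruit_colour(c("pink", "green")), "conspicuous")
  expect_error(classify_fruit_colour(character(0)), "non-empty")
  expect_error(classify_fruit_colour("magenta"), "unknown colour")
})

test_that("classification agrees with an independent rule table over all
          colour sets up to size 3", {
  vocab <- palmvision:::COLOUR_VOCAB
  # independently coded rule: palatability on the union first, then any
  # conspicuous colour triggers conspicuousness
  diet <- c("brown", "green", "orange", "yellow", "red", "purple")
  consp <- c("orange", "red", "yellow", "pink")
  rule <- function(set) {
    if (length(intersect(set, diet)) == 0) "excluded"
    else if (length(intersect(set, consp)) > 0) "conspicuous"
    else "non_conspicuous"
  }
  sets <- c(utils::combn(vocab, 1, simplify = FALSE),
            utils::combn(vocab, 2, simplify = FALSE),
            utils::combn(vocab, 3, simplify = FALSE))
  got <- vapply(sets, classify_fruit_colour, character(1))
  want <- vapply(sets, rule, character(1))
  expect_identical(got, want)
})

# Hand-enumerable toy fixture: 2 units, 4 primates, 5 palms.
toy_fixture <- function() {
  units <- data.frame(unit_id = c("u1", "u2"), temp = c(250, 200),
                      prec = c(1500, 900), tseas = c(200, 400),
                      pseas = c(50, 80), canopy = c(30, 12),
                      area = c(1e5, 2e5), realm = "Africa")
  primates <- data.frame(
    species_id = c("t1", "t2", "p1", "d1"),
    vision_system = c("routine_trichromatic", "routine_trichromatic",
                      "polymorphic", "dichromatic_or_monochromatic"),
    activity = c("diurnal", "nocturnal", "diurnal", "diurnal"),
    frugivory_rank = c(2, 3, 1, 0))
  palms <- data.frame(species_id = paste0("pa", 1:5),
                      colours = c("red", "orange", "yellow", "brown",
                                  "blue"))
  occ_p <- data.frame(unit_id = c("u1", "u1", "u1", "u1", "u2"),
                      species_id = c("t1", "t2", "p1", "d1", "t1"))
  occ_f <- data.frame(unit_id = c(rep("u1", 5), "u2", "u2"),
                      species_id = c(paste0("pa", 1:5), "pa4", "pa5"))
  list(units = units, primates = primates, palms = palms,
       occ_p = occ_p, occ_f = occ_f)
}

test_that("assemblage counts match manual enumeration on the toy fixture", {
  fx <- toy_fixture()
  a <- build_assemblage(fx$occ_p, fx$occ_f, fx$primates, fx$palms,
                        fx$units)
  # u1: 2 trichromats, 1 polymorph, 1 other; 3 conspicuous + 1 brown,
  # blue excluded -> prop = 3/4
  expect_equal(a$richness_trichromat, c(2L, 1L))
  expect_equal(a$richness_polymorph, c(1L, 0L))
  expect_equal(a$richness_other, c(1L, 0L))
  expect_equal(a$n_conspicuous, c(3L, 0L))
  expect_equal(a$n_nonconspicuous, c(1L, 1L))
  expect_equal(a$prop_conspicuous, c(0.75, 0))
  # richness classes always sum to the total primate richness
  expect_equal(a$richness_trichromat + a$richness_polymorph +
                 a$richness_other, c(4L, 1L))

  # the diurnal-frugivore subset drops the nocturnal trichromat t2 and the
  # non-frugivorous d1
  ad <- build_assemblage(fx$occ_p, fx$occ_f, fx$primates, fx$palms,
                         fx$units, subset = "diurnal_frugivores")
  expect_equal(ad$richness_trichromat, c(1L, 1L))
  expect_equal(ad$richness_polymorph, c(1L, 0L))
  expect_equal(ad$richness_other, c(0L, 0L))

  # duplicated occurrence rows do not change anything
  a2 <- build_assemblage(rbind(fx$occ_p, fx$occ_p),
                         rbind(fx$occ_f, fx$occ_f[1:3, ]),
                         fx$primates, fx$palms, fx$units)
  expect_equal(a2, a)

  # unknown species in occurrences is an error naming the offender
  bad <- rbind(fx$occ_p, data.frame(unit_id = "u1", species_id = "ghost"))
  expect_error(build_assemblage(bad, fx$occ_f, fx$primates, fx$palms,
                                fx$units), "ghost")
})

test_that("unit filtering applies the focal and palm-richness rules", {
  tab <- data.frame(unit_id = c("a", "b", "c", "d"),
                    richness_trichromat = c(0L, 1L, 1L, 2L),
                    richness_polymorph = c(2L, 0L, 0L, 1L),
                    richness_other = 0L,
                    n_conspicuous = c(3L, 1L, 2L, 4L),
                    n_nonconspicuous = c(2L, 1L, 1L, 0L),
                    prop_conspicuous = c(0.6, 0.5, 2 / 3, 1),
                    prop_defined = TRUE)
  f <- filter_units(tab, "trichromat")
  # a: 0 trichromats (dropped); b: 2 palms (dropped); c: 1 trichromat and
  # 3 palms (kept, boundary); d kept
  expect_equal(f$unit_id, c("c", "d"))
  f2 <- filter_units(tab, "trichromat_polymorph")
  expect_equal(f2$unit_id, c("a", "c", "d"))
})

test_that("variable transforms are sqrt/log then min-max", {
  tab <- data.frame(unit_id = letters[1:4],
                    richness_trichromat = c(0L, 1L, 4L, 9L),
                    area = c(exp(1), exp(2), exp(1.5), exp(1.2)),
                    temp = c(10, 20, 30, 40))
  out <- transform_variables(tab, vars = c("richness_trichromat", "area",
                                           "temp"))
  expect_equal(out$richness_trichromat, c(0, 1 / 3, 2 / 3, 1))
  expect_equal(out$log_area[1:2], c(0, 1))
  expect_equal(out$temp, c(0, 1, 2, 3) / 3)
  sc <- attr(out, "scaling")
  expect_equal(sc$transform, c("sqrt", "log", "none"))
  # inversion from the recorded constants
  expect_equal((out$richness_trichromat * (sc$max[1] - sc$min[1]) +
                  sc$min[1])^2, c(0, 1, 4, 9))

  tab$flat <- 5
  expect_error(transform_variables(tab, vars = c("temp", "flat")),
               "'flat'")
})

test_that("prop_conspicuous is undefined only without palatable palms", {
  fx <- toy_fixture()
  occ_f <- data.frame(unit_id = "u1", species_id = "pa5")  # blue only
  a <- build_assemblage(fx$occ_p, occ_f, fx$primates, fx$palms, fx$units)
  expect_true(is.na(a$prop_conspicuous[1]))
  expect_false(a$prop_defined[1])
  expect_true(all(a$prop_conspicuous >= 0 & a$prop_conspicuous <= 1,
                  na.rm = TRUE))
})
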