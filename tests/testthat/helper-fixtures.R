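# Small hand-built pedigree: 4 parents (2002), 6 offspring (2004), three
# full sibs of D1 x S1, one offspring with unknown dam.
toy_pedigree <- function() {
  as_pedigree(data.frame(
    id = c("D1", "D2", "S1", "S2", "O1", "O2", "O3", "O4", "O5", "O6"),
    sex = c("female", "female", "male", "male",
            "female", "male", "male", "female", "male", "male"),
    tactic = c("female", "female", "hooknose", "jack",
               "female", "hooknose", "jack", "female", "jack", "hooknose"),
    year = c(2002L, 2002L, 2002L, 2002L, rep(2004L, 6)),
    length_mm = c(700, 650, 750, 430, 720, 740, 450, 680, 440, 760),
    rs = c(3L, 2L, 4L, 1L, 2L, 0L, 1L, 3L, 0L, 2L),
    dam_id = c(NA, NA, NA, NA, "D1", "D1", "D1", "D2", "D2", NA),
    sire_id = c(NA, NA, NA, NA, "S1", "S1", "S1", "S2", "S2", "S1"),
    stringsAsFactors = FALSE))
}

# standardized-record data frame straight from vectors (bypasses pedigree)
records_from <- function(length_mm, rs, tactic = "female", year = 2002L) {
  standardize(data.frame(id = sprintf("i%d", seq_along(length_mm)),
                         tactic = tactic, year = year,
                         length_mm = length_mm, rs = rs,
                         stringsAsFactors = FALSE))
}

# parents-only pedigree from per-tactic length vectors
make_length_pedigree <- function(lengths_by_tactic) {
  rows <- do.call(rbind, lapply(names(lengths_by_tactic), function(t) {
    x <- lengths_by_tactic[[t]]
    data.frame(id = sprintf("%s%d", substr(t, 1, 1), seq_along(x)),
               sex = if (t == "female") "female" else "male",
               tactic = t, year = 2002L, length_mm = x,
               rs = rpois(length(x), 2), dam_id = NA, sire_id = NA,
               stringsAsFactors = FALSE)
  }))
  as_pedigree(rows)
}

# quick simulated pedigree with overridable config fields
quick_sim <- function(seed, ...) {
  simulate_pedigree(sim_config(seed = seed, ...))
}

# pedigree in which each dam has 3 daughters whose lengths reproduce the
# dam's length exactly (perfect parent-offspring resemblance)
clone_pedigree <- function(n_dams = 10) {
  dam_len <- seq(600, 800, length.out = n_dams)
  dams <- data.frame(id = sprintf("D%d", 1:n_dams), sex = "female",
                     tactic = "female", year = 2002L, length_mm = dam_len,
                     rs = 3L, dam_id = NA, sire_id = NA,
                     stringsAsFactors = FALSE)
  sires <- data.frame(id = "S1", sex = "male", tactic = "hooknose",
                      year = 2002L, length_mm = 700, rs = 3L * n_dams,
                      dam_id = NA, sire_id = NA, stringsAsFactors = FALSE)
  off <- do.call(rbind, lapply(1:n_dams, function(i)
    data.frame(id = sprintf("O%d_%d", i, 1:3), sex = "female",
               tactic = "female", year = 2004L,
               length_mm = dam_len[i] + c(-5, 0, 5), rs = 1L,
               dam_id = sprintf("D%d", i), sire_id = "S1",
               stringsAsFactors = FALSE)))
  as_pedigree(rbind(dams, sires, off))
}
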