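# Biochemical scope: per-generation expansion from each dietary entry
# point, encounter generations of other dietary compounds, and the
# accessible/inaccessible partition at the default 3-reaction horizon.

source("analysis/00_config.R")

w <- analysis_world()

profiles <- NULL
encounters <- NULL
for (d in w$global$dietary) {
  sc <- scope_expansion(w$global, d)
  profiles <- rbind(profiles, cbind(seed_compound = d, sc$profile))
  enc <- sc$encounter_generation
  enc <- enc[is.finite(enc)]
  if (length(enc))
    encounters <- rbind(encounters,
                        data.frame(seed_compound = d,
                                   encountered = names(enc),
                                   generation = unname(enc)))
}
write.csv(profiles, file.path(OUT, "scope_profiles.csv"), row.names = FALSE)
write.csv(encounters, file.path(OUT, "encounter_generations.csv"),
          row.names = FALSE)

cov <- tapply(profiles$n_compounds, profiles$seed_compound, max)
cat(sprintf("scope sizes per dietary entry: %d .. %d of %d compounds\n",
            min(cov), max(cov), nrow(w$global$compounds)))
cat(sprintf("%d dietary-encounter events; median encounter generation %.0f\n",
            nrow(encounters), median(encounters$generation)))

hz <- accessible_horizon(w$global, w$global$dietary[1], cutoff = 3)
cat(sprintf("from %s alone, %d compounds accessible and %d inaccessible at a 3-reaction horizon\n",
            w$global$dietary[1], length(hz$accessible),
            length(hz$inaccessible)))
write.csv(data.frame(compound = names(hz$counter),
                     counter = unname(hz$counter),
                     accessible = is.finite(hz$counter)),
          file.path(OUT, "accessible_horizon.csv"), row.names = FALSE)
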