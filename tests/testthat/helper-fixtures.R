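# shared fixtures, built once per test run
the_montage <- load_montage()

# one cached brief-profile session per group, for tests that only need
# "a realistic session" rather than fresh randomness
cached_session <- local({
  cache <- new.env(parent = emptyenv())
  function(nerve_block = FALSE, seed = 101) {
    key <- paste0(nerve_block, "_", seed)
    if (is.null(cache[[key]])) {
      set.seed(seed)
      cache[[key]] <- simulate_session(sim_config("brief"), the_montage,
                                       nerve_block = nerve_block,
                                       laterality = "R")
    }
    cache[[key]]
  }
})

write_events_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# montage JSON copy with an edit applied to the parsed structure
edited_montage_json <- function(edit) {
  m <- jsonlite::fromJSON(default_montage_path(), simplifyDataFrame = TRUE)
  m <- edit(m)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(m, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  path
}
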