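# Objects shared across test files; built once per session.
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

surrogate_waveform <- function() cached("waveform", generate_waveform())

# 100 s reference runs reused by several tests
sim_rate <- function(mutation, tone, duration_s = 100) {
  key <- paste("rate", if (is.null(mutation)) "WT" else mutation,
               tone, duration_s, sep = "_")
  cached(key, {
    cfg <- cell_config(mutation = mutation, tone = tone,
                       duration_s = duration_s)
    simulate_cell(cfg)$metrics$beating_rate
  })
}

vagal_rate_table <- function() cached("vagal_rates", {
  lib <- hcn4_mutations()
  tibble::tibble(
    name = c("WT", lib$name),
    beating_rate = c(sim_rate(NULL, "vagal"),
                     vapply(lib$name, sim_rate, numeric(1), tone = "vagal"))
  )
})
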