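# Shared synthetic survey dataset, generated once per test run. Three
# species cover the main behaviors: a two-paralog species with a
# colocalized phaE-phaC pair, a single-paralog species with a truncated
# homolog, and a weak-only species.

survey_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    refs <- example_reference_set()
    truths <- list(
      survey_truth("Haloferax duplexa",
                   data.frame(class = c("PhaC1", "PhaC3"),
                              identity = c(80, 72)),
                   phaE_present = TRUE, phaE_to_phaC_distance = 50),
      survey_truth("Halobacterium truncatum",
                   data.frame(class = "PhaC_Hme", identity = 90,
                              truncation = 0.62)),
      survey_truth("Natronomonas debilis",
                   data.frame(class = "PhaC2", identity = 55)))
    dir <- file.path(tempdir(), "halopha-survey-fixture")
    ds <- generate_survey_dataset(truths, refs, dir = dir,
                                  seed = 20260926L, n_decoys = 8L)
    res <- run_survey(refs, ds$proteome_paths, ds$loci_path,
                      out_dir = file.path(dir, "out"))
    cache <<- list(refs = refs, truths = truths, ds = ds, res = res,
                   dir = dir)
    cache
  }
})
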