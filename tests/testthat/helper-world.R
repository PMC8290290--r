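# Shared synthetic worlds, built once per test run and cached.

.world_env <- new.env(parent = emptyenv())

cached_world <- function(key, expr) {
  if (!exists(key, envir = .world_env)) {
    assign(key, force(expr), envir = .world_env)
  }
  get(key, envir = .world_env)
}

# compact family so detection worlds stay small: 400 bp LTRs, 4.4 kb
# elements, inter-LTR start distance 4 kb (inside the 3-25 kb window)
test_family <- function() {
  ltr_family("Fam1", ltr_len = 400, total_len = 4400, tsd_len = 5)
}

# clean world: 8 elements + 2 solos + 6 genes in ~300 kb
small_world <- function() {
  cached_world("small", {
    simulate_genome(length = 3e5, n_elements = 8, n_solos = 2, n_genes = 6,
                    families = list(test_family()),
                    age_range = c(2e5, 1.5e6), seed = 101)
  })
}

small_world_annotated <- function() {
  cached_world("small_ann", {
    w <- small_world()
    c(w, list(ann = annotate_ltr(w$genome, w$truth$domains)))
  })
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
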