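#' Read a model configuration from YAML
#'
#' Loads a structured configuration block into model objects. Expected keys:
#' `belief` (list of `weight`/`mu`/`sigma` entries, or a single `mu`/`sigma`
#' pair), `prior` (probability), `policy` (`beta`, `tau`, `horizon`,
#' `reward_magnitude`) and `mapping` (`kind`, optional `target`). Missing
#' keys fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `belief`, `prior`, `policy`, `mapping`.
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configurations requires the 'yaml' package.")
  }
  cfg <- yaml::read_yaml(path)
  belief <- if (is.null(cfg$belief)) {
    timing_belief(3, 2)
  } else if (!is.null(cfg$belief$mu)) {
    timing_belief(cfg$belief$mu, cfg$belief$sigma)
  } else {
    comps <- purrr::transpose(cfg$belief)
    timing_belief(unlist(comps$mu), unlist(comps$sigma), unlist(comps$weight))
  }
  pol <- cfg$policy %||% list()
  policy <- decision_policy(
    beta = pol$beta %||% 50, tau = pol$tau %||% 0.1,
    horizon = pol$horizon %||% 60, reward_magnitude = pol$reward_magnitude %||% 1
  )
  map <- cfg$mapping %||% list()
  mapping <- stim_mapping(map$kind %||% "polynomial", target = map$target)
  prior <- cfg$prior %||% 0.75
  check_probability(prior, "prior")
  list(belief = belief, prior = prior, policy = policy, mapping = mapping)
}
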