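# Background lexicon: neutral Dutch-style paediatric-consultation
# vocabulary carrying no class signal. Deliberately disjoint from the
# signal lexicons and (mostly) from the stop word list.
default_background_tokens <- function() {
  c("moeder", "vader", "ouders", "broer", "zus", "school", "juf", "meester",
    "thuis", "huisarts", "kinderarts", "verwijzing", "gesprek", "verhaal",
    "ochtend", "middag", "avond", "nacht", "dag", "dagen", "week", "weken",
    "maand", "maanden", "jaar", "keer", "keren", "minuten", "seconden",
    "uur", "kind", "jongen", "meisje", "baby", "peuter", "kleuter",
    "zwangerschap", "geboorte", "bevalling", "ontwikkeling", "groei",
    "eten", "drinken", "slapen", "wakker", "moe", "ziek", "gezond",
    "koorts", "verkouden", "hoesten", "griep", "oorontsteking",
    "medicatie", "paracetamol", "vitamine", "allergie", "astma", "eczeem",
    "voorgeschiedenis", "familie", "opa", "oma", "neef", "nicht",
    "speelt", "spelen", "buiten", "binnen", "fietsen", "zwemmen",
    "sporten", "televisie", "tablet", "eetlust", "gewicht", "lengte",
    "hoofd", "buik", "rug", "nek", "keel", "neus", "oor", "huid",
    "bleek", "warm", "koud", "pijn", "hoofdpijn", "buikpijn", "misselijk",
    "braken", "diarree", "obstipatie", "plassen", "ontlasting",
    "val", "vallen", "gevallen", "gestoten", "bult", "blauwe", "plek",
    "schaafwond", "consult", "onderzoek", "controle", "vragen",
    "antwoord", "zorgen", "ongerust", "gerust", "normaal", "goed",
    "slecht", "soms", "vaak", "zelden", "regelmatig", "plotseling",
    "geleidelijk", "kort", "lang", "even", "daarna", "daarvoor",
    "tijdens", "vandaag", "gisteren", "vorige", "volgende", "speelgoed",
    "vriendjes", "logeren", "vakantie", "weekend", "druk", "rustig",
    "vrolijk", "verdrietig", "boos", "één", "twee", "drie", "vier",
    "vijf", "tien", "beschrijft", "vertelt", "merkt", "ziet", "hoort",
    "voelt", "duurde", "begon", "stopte", "herstelde", "erna", "eerder",
    "sindsdien", "episode", "episodes", "moment", "momenten", "situatie",
    "aanleiding", "beloop", "klachten", "klacht", "periode", "thuissituatie",
    "crèche", "groep", "leerkracht", "huiswerk", "concentratie", "geheugen")
}

# Epilepsy-leaning signal items (unigrams and two-word phrases) with
# per-item rate multipliers: the item's occurrence rate in epilepsy
# letters is multiplier x its base rate. Phrases exercise the bigram
# machinery and the stop-word retention rules.
default_epilepsy_signal <- function() {
  tibble::tibble(
    item = c("trekkingen", "schokken", "kwijlde", "kwijlen", "tongbeet",
             "staren", "wegraking", "wegrakingen", "verstijfd",
             "verstijving", "absence", "absences", "schuim", "smakken",
             "grimassen", "automatismen", "ritmisch", "verkrampt",
             "trekken", "schokje", "starend", "afwezig", "aanvalletje",
             "spray", "incontinent",
             "haar mond", "geen reactie", "niet aanspreekbaar",
             "laatste dagen", "doorgemaakte aanval", "onduidelijke spraak"),
    multiplier = c(5, 5, 6, 4, 6,
                   4, 5, 4, 4,
                   4, 6, 5, 5, 5,
                   4, 6, 5, 4,
                   3, 3, 4, 3, 3,
                   4, 5,
                   4, 4, 4,
                   3, 5, 4))
}

# Non-epilepsy-leaning signal items (syncope / behavioural / febrile
# convulsion vocabulary).
default_control_signal <- function() {
  tibble::tibble(
    item = c("flauwvallen", "flauwgevallen", "wegzakken", "duizelig",
             "duizeligheid", "hyperventilatie", "driftbui", "driftbuien",
             "huilbui", "woedeaanval", "ademhaling", "koortsstuip",
             "koortsconvulsie", "reflex", "syncope", "collaps",
             "spanning", "stress", "zweten", "bang", "schrik",
             "schrikken", "hangerig", "slap", "bleekheid",
             "bij opstaan", "geen koorts", "na inspanning", "zijn ogen",
             "warme douche", "lange tijd"),
    multiplier = c(5, 4, 4, 3,
                   4, 6, 5, 4,
                   4, 5, 3, 5,
                   5, 3, 6, 5,
                   3, 4, 3, 3, 4,
                   3, 3, 3, 3,
                   4, 3, 4, 3,
                   4, 3))
}

#' Default synthetic vocabulary specification
#'
#' The lexicons and rates from which synthetic letters are drawn: a
#' neutral background lexicon, a stop word lexicon with Zipf-decaying
#' frequencies (so letters have realistic function-word scaffolding), and
#' two class-signal lexicons of unigrams and two-word phrases with
#' per-item rate multipliers (the effect sizes). Negation phrases
#' ("geen koorts"), whitelisted phrases ("bij opstaan") and
#' pronoun + clinical-noun phrases ("haar mond", "zijn ogen") are all
#' present so that every bigram-retention mechanism is genuinely
#' exercised by default data.
#'
#' @param background Character vector of background tokens.
#' @param stopwords Stop word lexicon (default: the shipped Dutch list).
#' @param epilepsy_signal,control_signal Tibbles `(item, multiplier)`.
#' @param background_mass,stopword_mass Unnormalized probability mass of
#'   the background / stop word lexicons (defaults 0.55 / 0.40).
#' @param signal_base_rate Per-item base occurrence rate before the
#'   multiplier (default 1e-4).
#' @return A `vocab_spec` list.
#' @export
vocab_spec <- function(background = default_background_tokens(),
                       stopwords = default_stopwords(),
                       epilepsy_signal = default_epilepsy_signal(),
                       control_signal = default_control_signal(),
                       background_mass = 0.55,
                       stopword_mass = 0.40,
                       signal_base_rate = 3e-4) {
  background <- setdiff(unique(background), stopwords)
  structure(list(background = background, stopwords = unique(stopwords),
                 epilepsy_signal = epilepsy_signal,
                 control_signal = control_signal,
                 background_mass = background_mass,
                 stopword_mass = stopword_mass,
                 signal_base_rate = signal_base_rate),
            class = "vocab_spec")
}

#' Synthetic corpus configuration
#'
#' Defines the study conditions the generator emulates: two sites with
#' unequal sizes (1250:311), final-diagnosis mix 32.9% epilepsy / 61.4%
#' no epilepsy / 5.7% unclear, a 25.6% initially-unclear stratum, and
#' letter lengths from a log-normal model calibrated so the median and
#' mean word counts match the printed 400 / 414 (sigma^2 =
#' 2 ln(mean/median)), truncated to 63-1070 words. Letters that are
#' 'unclear' at the first visit carry attenuated class signal: each
#' multiplier m becomes m^ambiguity_shrink, so shrink = 1 leaves effect
#' sizes untouched and smaller values blur the classes. Letters whose
#' *final* diagnosis is unclear are drawn from a 50/50 mixture of the
#' two class distributions (they are never used as binary labels).
#'
#' @param n_letters Number of letters (default 1561).
#' @param site_props Probabilities over `site_A` / `site_B`.
#' @param final_dx_props Probabilities over the three final diagnoses.
#' @param p_initial_unclear Overall probability a letter is unclear at
#'   the first visit. Final-unclear letters are always initially
#'   unclear; definitive letters receive the adjusted rate so the
#'   overall proportion matches.
#' @param length_model List with `min_words`, `max_words`,
#'   `median_target`, `mean_target`.
#' @param vocab A [vocab_spec()].
#' @param ambiguity_shrink Effect-size shrink factor in (0, 1] for
#'   initially-unclear letters (default 0.5).
#' @param site_skew Optional per-site background skew in [0, 1); 0
#'   (default) makes the two sites linguistically identical.
#' @param seed Integer seed; identical config and seed give a
#'   byte-identical corpus.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_letters = 1561L,
                         site_props = c(site_A = 1250 / 1561,
                                        site_B = 311 / 1561),
                         final_dx_props = c(epilepsy = 0.329,
                                            no_epilepsy = 0.614,
                                            unclear = 0.057),
                         p_initial_unclear = 0.256,
                         length_model = list(min_words = 63L,
                                             max_words = 1070L,
                                             median_target = 400,
                                             mean_target = 414),
                         vocab = vocab_spec(),
                         ambiguity_shrink = 0.5,
                         site_skew = 0,
                         seed = 1L) {
  stopifnot(n_letters >= 1)
  if (abs(sum(site_props) - 1) > 1e-12) {
    stop("site_props must sum to 1", call. = FALSE)
  }
  if (abs(sum(final_dx_props) - 1) > 1e-12) {
    stop("final_dx_props must sum to 1", call. = FALSE)
  }
  stopifnot(p_initial_unclear >= 0, p_initial_unclear <= 1,
            ambiguity_shrink > 0, ambiguity_shrink <= 1)
  lm <- length_model
  if (!(lm$min_words <= lm$median_target && lm$median_target <= lm$max_words)) {
    stop("infeasible length model: median_target must lie in [min_words, max_words]",
         call. = FALSE)
  }
  if (lm$mean_target < lm$median_target) {
    stop("length model requires mean_target >= median_target (right-skewed lengths)",
         call. = FALSE)
  }
  sig_items <- c(vocab$epilepsy_signal$item, vocab$control_signal$item)
  overlap <- intersect(sig_items, vocab$stopwords)
  if (length(overlap)) {
    stop("signal lexicons must be disjoint from the stopword lexicon: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(n_letters = as.integer(n_letters),
                 site_props = site_props,
                 final_dx_props = final_dx_props,
                 p_initial_unclear = p_initial_unclear,
                 length_model = lm,
                 vocab = vocab,
                 ambiguity_shrink = ambiguity_shrink,
                 site_skew = site_skew,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Write / read a synthetic configuration as YAML
#'
#' Scalar parameters and the signal lexicons round-trip through YAML;
#' lexicons omitted from a file fall back to the package defaults.
#'
#' @param config A [synth_config()].
#' @param path YAML file path.
#' @return `write_synth_config()` returns `path` invisibly;
#'   `read_synth_config()` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  out <- list(
    n_letters = config$n_letters,
    site_props = as.list(config$site_props),
    final_dx_props = as.list(config$final_dx_props),
    p_initial_unclear = config$p_initial_unclear,
    length_model = config$length_model,
    ambiguity_shrink = config$ambiguity_shrink,
    site_skew = config$site_skew,
    seed = config$seed,
    vocab = list(
      background_mass = config$vocab$background_mass,
      stopword_mass = config$vocab$stopword_mass,
      signal_base_rate = config$vocab$signal_base_rate,
      epilepsy_signal = as.list(stats::setNames(config$vocab$epilepsy_signal$multiplier,
                                                config$vocab$epilepsy_signal$item)),
      control_signal = as.list(stats::setNames(config$vocab$control_signal$multiplier,
                                               config$vocab$control_signal$item))
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  vs <- vocab_spec(
    background_mass = y$vocab$background_mass,
    stopword_mass = y$vocab$stopword_mass,
    signal_base_rate = y$vocab$signal_base_rate,
    epilepsy_signal = tibble::tibble(item = names(y$vocab$epilepsy_signal),
                                     multiplier = as.numeric(unlist(y$vocab$epilepsy_signal))),
    control_signal = tibble::tibble(item = names(y$vocab$control_signal),
                                    multiplier = as.numeric(unlist(y$vocab$control_signal)))
  )
  synth_config(n_letters = y$n_letters,
               site_props = unlist(y$site_props),
               final_dx_props = unlist(y$final_dx_props),
               p_initial_unclear = y$p_initial_unclear,
               length_model = y$length_model,
               vocab = vs,
               ambiguity_shrink = y$ambiguity_shrink,
               site_skew = y$site_skew %||% 0,
               seed = y$seed)
}
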