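# Shared fixture loaders: every test file reads the packaged campaign
# tables through the public API.
fx_traits <- function() read_trait_table(pgp_fixture("traits"))
fx_inhibition <- function() read_inhibition_matrix(pgp_fixture("inhibition"))
fx_roster <- function() read_roster(pgp_fixture("roster"))
fx_published <- function() read_published_scores(pgp_fixture("bonitur_published"))

# A maximal and a null trait profile for boundary tests.
profile_row <- function(iaa = NA, p_solub = NA, ammonia = NA,
                        siderophore = NA, n2_fixation = FALSE,
                        acc_deaminase = FALSE, chitinase = FALSE,
                        protease = FALSE, cellulase = FALSE,
                        pectinase = FALSE, id = "X1") {
  data.frame(isolate_id = id, iaa = iaa, p_solub = p_solub,
             ammonia = ammonia, siderophore = siderophore,
             n2_fixation = n2_fixation, acc_deaminase = acc_deaminase,
             chitinase = chitinase, protease = protease,
             cellulase = cellulase, pectinase = pectinase,
             stringsAsFactors = FALSE)
}
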