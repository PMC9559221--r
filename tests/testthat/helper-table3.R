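# Expected per-row verdicts for the bundled worked cohort, derived by hand
# from the printed donor typings, panel annotations and assignment rules:
# LR = first-field match at A/B/DRB1, exact two-field match at imputed C/DQ,
# unclassifiable at DP; HR = two-field chain-level match with panel awareness.
expected_table3_verdicts <- function() {
  v <- function(spec_id, lr, hr) data.frame(spec_id = spec_id, lr = lr, hr = hr,
                                            stringsAsFactors = FALSE)
  rbind(
    v("1.1", "DSA", "not_DSA"),
    v("2.1", "DSA", "not_DSA"),
    v("3.1", "DSA", "not_DSA"),
    v("4.1", "DSA", "unassessable_panel"),
    v("5.1", "DSA", "unassessable_panel"),
    v("6.1", "DSA", "unassessable_panel"),
    v("7.1", "DSA", "unassessable_panel"),
    v("8.1", "DSA", "DSA"),
    v("9.1", "DSA", "DSA"),
    v("10.1", "DSA", "DSA"),
    v("10.2", "DSA", "DSA"),
    v("11.1", "DSA", "DSA"),
    v("12.1", "DSA", "DSA"),
    v("13.1", "DSA", "DSA"),
    v("14.1", "DSA", "DSA"),
    v("15.1", "DSA", "DSA"),
    v("15.2", "DSA", "DSA"),
    v("16.1", "DSA", "DSA"),
    v("17.1", "DSA", "DSA"),
    v("18.1", "DSA", "DSA"),
    v("19.1", "DSA", "DSA"),
    v("20.1", "DSA", "DSA"),
    v("21.1", "DSA", "DSA"),
    v("22.1", "DSA", "DSA"),
    v("23.1", "DSA", "DSA"),
    v("24.1", "DSA", "DSA"),
    v("24.2", "DSA", "DSA"),
    v("25.1", "DSA", "DSA"),
    v("26.1", "DSA", "DSA"),
    v("26.2", "DSA", "DSA"),
    v("27.1", "DSA", "DSA"),
    v("28.1", "not_DSA", "DSA"),
    v("29.1", "unclassifiable_typing", "DSA"),
    v("30.1", "unclassifiable_typing", "DSA"),
    v("31.1", "DSA", "DSA"),
    v("31.2", "not_DSA", "DSA"),
    v("31.3", "DSA", "not_DSA"),
    v("32.1", "DSA", "DSA"),
    v("32.2", "not_DSA", "DSA"),
    v("33.1", "DSA", "not_DSA"),
    v("33.2", "DSA", "DSA"),
    v("34.1", "DSA", "unassessable_panel"),
    v("34.2", "DSA", "DSA"),
    v("34.3", "unclassifiable_typing", "DSA"),
    v("34.4", "unclassifiable_typing", "DSA"),
    v("35.1", "DSA", "unassessable_panel"),
    v("35.2", "unclassifiable_typing", "DSA"),
    v("36.1", "DSA", "DSA"),
    v("36.2", "DSA", "not_DSA"),
    v("36.3", "DSA", "DSA"),
    v("37.1", "DSA", "DSA"),
    v("37.2", "DSA", "not_DSA"),
    v("37.3", "DSA", "DSA"),
    v("38.1", "DSA", "unassessable_panel"),
    v("38.2", "DSA", "DSA"),
    v("38.3", "DSA", "DSA"),
    v("39.1", "DSA", "DSA"),
    v("39.2", "DSA", "not_DSA"))
}
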