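# Construct a single-row isolate assay record with sensible defaults.
make_isolate <- function(id = "i1", a136 = FALSE, produced = "",
                         res = c(0.95, 0.95, 0.95), ctrl = 0.95, ph = 7.0) {
  tibble::tibble(
    isolate_id = id, a136_positive = a136, cv026_positive = FALSE,
    jba357_positive = FALSE, produced_ahls = produced,
    residual_3OC6 = res[1], residual_3OC8 = res[2], residual_3OC12 = res[3],
    control_3OC6 = ctrl, control_3OC8 = ctrl, control_3OC12 = ctrl,
    control_ph = ph
  )
}
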