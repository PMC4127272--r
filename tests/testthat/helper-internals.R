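# Internal functions exercised directly by unit tests.
varint_encode <- sbpnn:::varint_encode
varint_decode <- sbpnn:::varint_decode
new_artifact <- sbpnn:::new_artifact
new_artifact_stream <- sbpnn:::new_artifact_stream
model_mse <- sbpnn:::model_mse
hidden_quantize <- sbpnn:::hidden_quantize
hidden_dequantize <- sbpnn:::hidden_dequantize
round_half_away <- sbpnn:::round_half_away
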