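landmarks.csv: frame (0-based), time_s (s), <landmark>_x/_y (cm) for left_ear, right_ear, spine
speed.csv: frame, time_s (s), speed_cms (oriented speed, cm/s), state (forward/stationary/backward)
traces.csv: time_s (s), one dF/F column per cell_id (20 Hz)
events.csv: event (stop/long_stop/start/grooming), onset_s, onset_frame (0-based, behaviour clock), offset_s, provenance
cells.csv: cell_id, cell_class, reliability_p, response_amp (a.u./s), sustained, location (medial/lateral)
schedule.csv: state, start_s, end_s (s)
config.json: simulation configuration (see ?sim_config)
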