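{
  "Liolaemidae": ["Ctenoblepharys", "Phymaturus", "chiliensis", "lineomaculatus", "montanus", "boulengeri"],
  "Ctenoblepharys": ["Ctenoblepharys"],
  "Phymaturus": ["Phymaturus"],
  "Liolaemus": ["chiliensis", "lineomaculatus", "montanus", "boulengeri"],
  "Chiliensis": ["chiliensis"],
  "Eulaemus": ["lineomaculatus", "montanus", "boulengeri"],
  "lineomaculatus": ["lineomaculatus"],
  "montanus_boulengeri": ["montanus", "boulengeri"],
  "montanus": ["montanus"],
  "boulengeri": ["boulengeri"]
}
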