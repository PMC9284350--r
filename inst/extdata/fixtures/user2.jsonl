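{"user_id":"user2","post_id":"user2-p1","created_at":"2020-06-01T12:00:00Z","text":"5yo called me fat after I told 2.5yo I was too large to fit between their seats because of the baby. #37weekspregnant"}
{"user_id":"user2","post_id":"user2-p2","created_at":"2020-03-26T12:00:00Z","text":"I saw the MFM and cardiologist last week. It was determined my cardiomyopathy is manageable and I was put on a beta blocker"}
{"user_id":"user2","post_id":"user2-p3","created_at":"2020-06-11T12:00:00Z","text":"Introducing [name] 7lbs 5oz 20” long Csection went really well. We can’t wait until the big boys get to meet him"}
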