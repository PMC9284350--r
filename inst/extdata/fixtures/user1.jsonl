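{"user_id":"user1","post_id":"user1-p1","created_at":"2020-01-25T12:00:00Z","text":"exactly 100 days til my due date!"}
{"user_id":"user1","post_id":"user1-p2","created_at":"2020-04-16T12:00:00Z","text":"I was on Propranolol during my pregnancy and I had the CRAZIEST dreams I swear"}
{"user_id":"user1","post_id":"user1-p3","created_at":"2020-04-03T12:00:00Z","text":"Officially introducing [name], born April 2nd, 2020. 4lbs 12oz, 18”. She’s in NICU due to being premature, but she’s doing well!"}
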