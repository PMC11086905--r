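"item_id","text","criterion","reverse_coded"
"SCI-1","Woke from sleep tired and unrefreshed","B3",FALSE
"SCI-2","Mind crowded by unwanted thoughts","B2",FALSE
"SCI-3","Head full of many thoughts","B2",FALSE
"SCI-4","Felt there was no exit","A",FALSE
"SCI-5","Sudden waves of negative emotion","B1",FALSE
"SCI-6","Entrapment domain item (synthetic filler)","A",FALSE
"SCI-7","Inner pain too great to bear","B1",FALSE
"SCI-8","Could not switch off thinking","B2",FALSE
"SCI-9","Entrapment domain item (synthetic filler)","A",FALSE
"SCI-10","Affective Disturbance domain item (synthetic filler)","B1",FALSE
"SCI-11","Hard to stop worrying","B2",FALSE
"SCI-12","Felt hopeless","A",FALSE
"SCI-13","Felt there was no way out","A",FALSE
"SCI-14","Trouble thinking or concentrating from too many thoughts","B2",FALSE
"SCI-15","Loss of Cognitive Control domain item (synthetic filler)","B2",FALSE
"SCI-16","Affective Disturbance domain item (synthetic filler)","B1",FALSE
"SCI-17","Entrapment domain item (synthetic filler)","A",FALSE
"SCI-18","Hyperarousal domain item (synthetic filler)","B3",FALSE
"SCI-20","Loss of Cognitive Control domain item (synthetic filler)","B2",FALSE
"SCI-21","Affective Disturbance domain item (synthetic filler)","B1",FALSE
"SCI-22","Entrapment domain item (synthetic filler)","A",FALSE
"SCI-23","Hyperarousal domain item (synthetic filler)","B3",FALSE
"SCI-24","Thoughts were racing","B2",FALSE
"SCI-26","Looping thoughts that would not stop","B2",FALSE
"SCI-27","Loss of Cognitive Control domain item (synthetic filler)","B2",FALSE
"SCI-28","Affective Disturbance domain item (synthetic filler)","B1",FALSE
"SCI-29","Entrapment domain item (synthetic filler)","A",FALSE
"SCI-30","Felt trapped with no good options","A",FALSE
"SCI-31","Hyperarousal domain item (synthetic filler)","B3",FALSE
"SCI-32","Loss of Cognitive Control domain item (synthetic filler)","B2",FALSE
"SCI-33","Affective Disturbance domain item (synthetic filler)","B1",FALSE
"SCI-34","Ideas turning over and over in the mind","B2",FALSE
"SCI-35","Felt doomed","A",FALSE
"SCI-36","Entrapment domain item (synthetic filler)","A",FALSE
"SCI-37","Emotional pain colored everything","B1",FALSE
"SCI-38","Inner pain that had to be stopped","B1",FALSE
"SCI-39","Loss of Cognitive Control domain item (synthetic filler)","B2",FALSE
"SCI-40","Affective Disturbance domain item (synthetic filler)","B1",FALSE
"SCI-41","Emotional pain felt unbearable","B1",FALSE
"SCI-42","Hyperarousal domain item (synthetic filler)","B3",FALSE
"SCI-44","Entrapment domain item (synthetic filler)","A",FALSE
"SCI-45","Pressure in the head from overthinking","B2",FALSE
"SCI-46","Affective Disturbance domain item (synthetic filler)","B1",FALSE
"SCI-47","Headache from too many thoughts","B2",FALSE
"SCI-48","Urge to escape the pain was hard to control","B1",FALSE
"SCI-49","Hyperarousal domain item (synthetic filler)","B3",FALSE
"SCI-50","Social Withdrawal domain item (synthetic filler)","B4",FALSE
"SCI-51","Intense negative feelings directed at oneself","B1",FALSE
"SCI-52","Social Withdrawal domain item (synthetic filler)","B4",FALSE
"SCI-53","Social Withdrawal domain item (synthetic filler)","B4",FALSE
"SCI-54","Dissatisfied or bored with everything","B1",FALSE
"SCI-55","Social Withdrawal domain item (synthetic filler)","B4",FALSE
"SCI-56","Social Withdrawal domain item (synthetic filler)","B4",FALSE
"SCI-57","Enjoyed being with family or close friends","B1",TRUE
"SCI-58","Social Withdrawal domain item (synthetic filler)","B4",FALSE
"SCI-59","So restless could not sit still","B3",FALSE
"SCI-60","Wanted to crawl out of own skin","B3",FALSE
"SCI-61","Stirred up inside to the point of screaming","B3",FALSE
"SCI-62","Social Withdrawal domain item (synthetic filler)","B4",FALSE
"SCI-72","Easily annoyed or irritated","B3",FALSE
"SCI-74","Did not open up to family or friends","B4",FALSE
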